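test_that("peptide normalization produces relative signals and is idempotent", {
  meta <- data.frame(channel = c("c1", "c2"), area_um2 = c(3, 3))
  tab <- data.frame(peptide_id = c("a", "b"), protein_id = "P1",
                    c1 = c(5, 2), c2 = c(5, 4))
  n1 <- normalize_peptides(tab, meta)
  expect_equal(as.numeric(n1$peptides[1, c("c1", "c2")]), c(1, 1))
  expect_equal(as.numeric(n1$peptides[2, c("c1", "c2")]), c(2 / 3, 4 / 3))
  n2 <- normalize_peptides(n1$peptides, n1$meta)
  expect_equal(n2$peptides, n1$peptides, tolerance = 1e-12)
  # all-zero rows are dropped
  tab0 <- rbind(tab, data.frame(peptide_id = "z", protein_id = "P2",
                                c1 = 0, c2 = 0))
  expect_equal(normalize_peptides(tab0, meta)$dropped, 1)
  expect_error(normalize_peptides(tab, meta[1, ]), "2 channels")
})

test_that("protein slopes hit their defining cases and thresholds", {
  om <- sim_omics(1, peptides_per_entity = 5, true_slopes = 0, noise_cv = 0,
                  seed = 1)
  expect_equal(protein_slopes(om$peptides, om$meta)$slope, 0, tolerance = 1e-10)
  # halving per size doubling = slope -1
  om2 <- sim_omics(1, peptides_per_entity = 5, true_slopes = -1,
                   channel_areas = c(2, 4, 8), noise_cv = 0, seed = 2)
  expect_equal(protein_slopes(om2$peptides, om2$meta)$slope, -1,
               tolerance = 1e-10)
  # proteins below min_peptides are excluded
  om3 <- sim_omics(2, peptides_per_entity = c(2, 2), true_slopes = 0.5,
                   noise_cv = 0, seed = 3)
  expect_equal(nrow(protein_slopes(om3$peptides, om3$meta, min_peptides = 3)), 0)
})

test_that("protein slope recovery at realistic noise is accurate", {
  om <- sim_omics(200, peptides_per_entity = 10, noise_cv = 0.1, seed = 5)
  sl <- protein_slopes(om$peptides, om$meta)
  m <- merge(sl, om$truth, by = "protein_id")
  expect_equal(nrow(m), 200)
  expect_lt(sqrt(mean((m$slope.x - m$slope.y)^2)), 0.1)
  # a planted slope of 0.5 is recovered with ~0.05 accuracy per protein
  om5 <- sim_omics(20, peptides_per_entity = 10, true_slopes = 0.5,
                   noise_cv = 0.1, seed = 6)
  sl5 <- protein_slopes(om5$peptides, om5$meta)
  expect_lt(abs(mean(sl5$slope) - 0.5), 0.02)
  expect_lt(sqrt(mean((sl5$slope - 0.5)^2)), 0.05)
})

test_that("slopes are invariant to the scale factors normalization removes", {
  om <- sim_omics(30, peptides_per_entity = 5, noise_cv = 0.05, seed = 7)
  sl1 <- protein_slopes(om$peptides, om$meta)
  # per-peptide scale (ionization efficiency): removed by the relative signal
  pep <- om$peptides
  fac <- stats::runif(nrow(pep), 0.2, 5)
  for (ch in om$meta$channel) pep[[ch]] <- pep[[ch]] * fac
  expect_equal(protein_slopes(pep, om$meta)$slope, sl1$slope,
               tolerance = 1e-10)
  # per-channel scale (loading): removed by the channel-sum normalization
  scaled <- om$peptides
  for (i in seq_along(om$meta$channel))
    scaled[[om$meta$channel[i]]] <- scaled[[om$meta$channel[i]]] * (i * 2.5)
  n1 <- normalize_peptides(om$peptides, om$meta, normalize_channels = TRUE)
  n2 <- normalize_peptides(scaled, om$meta, normalize_channels = TRUE)
  expect_equal(protein_slopes(n2)$slope, protein_slopes(n1)$slope,
               tolerance = 1e-10)
})

test_that("replicate slopes from shared truth are strongly correlated", {
  om <- sim_omics(150, peptides_per_entity = 6, noise_cv = 0.15,
                  n_replicates = 2, seed = 8)
  sl <- protein_slopes(om$peptides, om$meta)
  expect_true(all(c("slope_rep1", "slope_rep2") %in% names(sl)))
  rho <- stats::cor(sl$slope_rep1, sl$slope_rep2, method = "spearman",
                    use = "complete.obs")
  expect_gte(rho, 0.9)
})

test_that("RNA slopes follow their definition and filtering", {
  areas <- c(2, 3, 4.5, 7)
  tpm <- rbind(gA = rep(50, 4), gB = 100 / areas, gC = c(0.2, 0.5, 0.3, 0.9))
  sl <- rna_slopes(tpm, areas, tpm_floor = 1)
  expect_equal(sl$slope[sl$gene_id == "gA"], 0, tolerance = 1e-10)
  expect_equal(sl$slope[sl$gene_id == "gB"], -1, tolerance = 1e-10)
  expect_false("gC" %in% sl$gene_id)       # below the TPM floor everywhere
})

test_that("RNA slope estimates track the generating slopes", {
  set.seed(9)
  n <- 300
  areas <- c(2, 3, 4.5, 7, 10)
  slopes <- rnorm(n, 0, 0.3)
  x <- areas / mean(areas)
  base <- 10^runif(n, 1, 3)
  tpm <- t(vapply(seq_len(n), function(i)
    base[i] * x^slopes[i] * rlnorm(length(x), 0, 0.1), numeric(length(x))))
  rownames(tpm) <- sprintf("g%03d", seq_len(n))
  sl <- rna_slopes(tpm, areas)
  m <- match(sl$gene_id, rownames(tpm))
  expect_gte(stats::cor(sl$slope, slopes[m], method = "spearman"), 0.95)
})

test_that("oriC circular distances match direct evaluation and symmetry", {
  expect_equal(oric_distance(3925859), 0)
  expect_equal(oric_distance(1), 715794)
  expect_equal(oric_distance(4641652), 715793)
  expect_error(oric_distance(0), "outside")
  # reflection about oriC on the circle preserves distance
  L <- 4641652; o <- 3925859
  set.seed(10)
  m <- sample.int(L, 200)
  refl <- ((2 * o - m - 1) %% L) + 1
  expect_equal(oric_distance(m), oric_distance(refl))
  # maximum over the circle is floor(L / 2)
  g <- oric_distance(seq.int(1, L, by = 1000))
  antipode <- ((o + L %/% 2 - 1) %% L) + 1
  expect_equal(max(oric_distance(c(g_max_probe = antipode))), L %/% 2)
  expect_lte(max(g), L %/% 2)
})

test_that("PCA summary reports the PC1 variance fraction", {
  # one varying direction: fraction 1
  v <- c(1, 2, 3, 4, 5)
  mat <- outer(rnorm(50), v)
  ps <- pca_summary(mat, areas = exp(v))
  expect_equal(ps$pc1_var_fraction, 1, tolerance = 1e-10)
  expect_equal(nrow(ps$projections), 5)
  # isotropic noise: fraction near 1/n_samples (random-matrix oracle band)
  set.seed(11)
  iso <- matrix(rnorm(2000 * 8), 2000, 8)
  frac <- pca_summary(iso, areas = rep(3, 8))$pc1_var_fraction
  oracle <- replicate(5, {
    m <- matrix(rnorm(2000 * 8), 2000, 8)
    p <- prcomp(t(m)); p$sdev[1]^2 / sum(p$sdev^2)
  })
  expect_lt(abs(frac - mean(oracle)), 4 * sd(oracle) + 0.02)
})

test_that("gene-set comparison behaves at both extremes", {
  sl <- data.frame(gene_id = sprintf("g%03d", 1:400),
                   slope = rep(c(-0.1, 0.1), 200))
  # in-set and out-set carry identical value multisets: p = 1
  same <- gene_set_compare(sl, sl$gene_id[1:200])
  expect_gt(same$p_value, 0.99)
  # shifted by +1: overwhelming significance
  sl2 <- sl
  inset <- sl2$gene_id[1:200]
  sl2$slope[1:200] <- sl2$slope[1:200] + 1
  shift <- gene_set_compare(sl2, inset)
  expect_lt(shift$p_value, 1e-10)
  expect_equal(shift$median_in - shift$median_out, 1)
  expect_error(gene_set_compare(sl, character(0)), "non-empty")
})

test_that("covariate correlation detects self-correlation and independence", {
  set.seed(12)
  sl <- data.frame(gene_id = sprintf("g%04d", 1:1000), slope = rnorm(1000))
  self <- correlate_covariate(sl, data.frame(gene_id = sl$gene_id,
                                             value = sl$slope))
  expect_equal(self$rho, 1)
  indep <- correlate_covariate(sl, data.frame(gene_id = sl$gene_id,
                                              value = rnorm(1000)))
  expect_lt(abs(indep$rho), 0.1)
  expect_gt(indep$p_value, 0.01)
  # subset rule restricts the sample
  sub <- correlate_covariate(sl, data.frame(gene_id = sl$gene_id,
                                            value = rnorm(1000)),
                             subset_rule = function(v) v > 0.7)
  expect_lt(sub$n, 1000)
})

test_that("MS1 abundance is summed intensity over protein length", {
  ints <- data.frame(protein_id = c("A", "A", "B"),
                     intensity = c(100, 200, 300))
  lens <- data.frame(protein_id = c("A", "B"), length = c(300, 150))
  ab <- ms1_abundance(ints, lens)
  expect_equal(ab$abundance[ab$protein_id == "A"], 1)
  expect_equal(ab$abundance[ab$protein_id == "B"], 2)
  ab2 <- ms1_abundance(transform(ints, intensity = intensity * 2), lens)
  expect_equal(ab2$abundance, ab$abundance * 2)
  expect_error(ms1_abundance(ints, data.frame(protein_id = "A", length = 0)),
               "> 0")
})

test_that("slope census counts strictly-inside-band entities", {
  cs <- slope_census(c(-0.3, -0.2, -0.1, 0, 0.19, 0.2, 0.5), band = 0.2)
  expect_equal(cs$n_within, 3)
  expect_equal(cs$n_total, 7)
})
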