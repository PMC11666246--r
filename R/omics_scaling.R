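#' Normalize a TMT peptide table to relative channel signals
#'
#' Per peptide, each channel intensity is divided by that peptide's mean
#' intensity across channels (missing values ignored), yielding the relative
#' signal y_i; per channel, the normalized cell size is
#' x_i = area_i / mean(areas). All-zero peptide rows are dropped.
#'
#' @param peptides data.frame with one intensity column per channel (named in
#'   `meta$channel`) plus identifier columns.
#' @param meta data.frame: channel (column name), area_um2; optionally
#'   replicate.
#' @param normalize_channels divide each channel by its summed intensity over
#'   all peptides first (equal-loading correction), which makes downstream
#'   slopes invariant to per-channel scale factors. Default FALSE: the
#'   per-peptide relative signal is computed on the raw reporter intensities.
#' @return list with `peptides` (relative signals in the channel columns),
#'   `meta` (with an `x` column of normalized sizes), `dropped` (row count).
#' @export
normalize_peptides <- function(peptides, meta, normalize_channels = FALSE) {
  if (nrow(meta) < 2) stop("need >= 2 channels")
  if (!all(meta$channel %in% names(peptides)))
    stop("missing channel columns: ",
         paste(setdiff(meta$channel, names(peptides)), collapse = ", "))
  m <- as.matrix(peptides[, meta$channel, drop = FALSE])
  m[m == 0] <- NA
  if (normalize_channels) {
    tot <- colSums(m, na.rm = TRUE)
    m <- sweep(m, 2, tot / mean(tot), "/")
  }
  rm_row <- rowSums(!is.na(m)) == 0
  m <- m[!rm_row, , drop = FALSE]
  peptides <- peptides[!rm_row, , drop = FALSE]
  rel <- m / rowMeans(m, na.rm = TRUE)
  peptides[, meta$channel] <- rel
  meta$x <- meta$area_um2 / mean(meta$area_um2)
  list(peptides = peptides, meta = meta, dropped = sum(rm_row))
}

# slope of log2(y) on log2(x); intercept free by default
.log2_slope <- function(y, x, intercept = TRUE) {
  ok <- is.finite(y) & y > 0 & is.finite(x) & x > 0
  if (sum(ok) < 2) return(NA_real_)
  ly <- log2(y[ok]); lx <- log2(x[ok])
  if (intercept) unname(stats::coef(stats::lm(ly ~ lx))[2])
  else unname(stats::coef(stats::lm(ly ~ 0 + lx))[1])
}

#' Per-protein size-scaling slopes from a normalized peptide table
#'
#' Peptide relative signals are consolidated per protein and channel by the
#' median; the protein slope is the coefficient of a linear fit of
#' log2(median relative signal) on log2(normalized cell size). Peptides with
#' the same sequence but different charge states or fractions count as
#' independent measurements; proteins with fewer than `min_peptides`
#' measurements are excluded. When `meta` has a `replicate` column, slopes
#' are computed per replicate and averaged.
#'
#' @param norm list from [normalize_peptides()], or raw peptides +
#'   `meta` (normalized internally).
#' @param meta channel metadata if `norm` is a raw data.frame.
#' @param min_peptides minimum independent peptide measurements per protein.
#'   Default 3.
#' @param intercept include a free intercept in the regression (default TRUE;
#'   per-peptide mean-normalization does not exactly center the logs).
#' @return data.frame: protein_id, slope, n_peptides, n_replicates, plus one
#'   `slope_rep<k>` column per replicate when replicates are present.
#' @export
protein_slopes <- function(norm, meta = NULL, min_peptides = 3,
                           intercept = TRUE) {
  if (is.data.frame(norm)) norm <- normalize_peptides(norm, meta)
  meta <- norm$meta
  peptides <- norm$peptides
  reps <- if ("replicate" %in% names(peptides)) sort(unique(peptides$replicate))
          else 1L
  use_rep_col <- "replicate" %in% names(peptides)
  rows <- list()
  for (pid in unique(peptides$protein_id)) {
    sub_all <- peptides[peptides$protein_id == pid, , drop = FALSE]
    rep_slopes <- rep(NA_real_, length(reps))
    for (ri in seq_along(reps)) {
      sub <- if (use_rep_col) sub_all[sub_all$replicate == reps[ri], , drop = FALSE]
             else sub_all
      if (nrow(sub) < min_peptides) next
      med <- apply(as.matrix(sub[, meta$channel, drop = FALSE]), 2,
                   stats::median, na.rm = TRUE)
      rep_slopes[ri] <- .log2_slope(med, meta$x, intercept)
    }
    if (all(is.na(rep_slopes))) next
    row <- data.frame(protein_id = pid,
                      slope = mean(rep_slopes, na.rm = TRUE),
                      n_peptides = nrow(sub_all),
                      n_replicates = sum(!is.na(rep_slopes)))
    if (length(reps) > 1)
      row[paste0("slope_rep", seq_along(reps))] <- as.list(rep_slopes)
    rows[[length(rows) + 1]] <- row
  }
  if (length(rows) == 0)
    return(data.frame(protein_id = character(0), slope = numeric(0),
                      n_peptides = integer(0), n_replicates = integer(0)))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Per-gene RNA size-scaling slopes from a TPM table
#'
#' TPM values are optionally recalculated after restricting to a gene subset
#' (e.g. the focal organism), then values below `tpm_floor` are removed. Per
#' gene, TPM values are normalized to the gene's mean and log2-transformed;
#' the same normalization is applied to the cell areas; the RNA slope is the
#' slope of the linear regression of the normalized log2 data.
#'
#' @param tpm matrix or data.frame, genes x samples (rownames = gene ids).
#' @param areas mean cell area per sample, um^2.
#' @param gene_subset optional character vector of gene ids to keep before
#'   re-normalizing TPM to 1e6 per sample.
#' @param tpm_floor values below this are treated as missing. Default 1.
#' @param intercept free intercept in the regression (default TRUE).
#' @return data.frame: gene_id, slope, n_samples. Genes below the floor in
#'   all (or all but one) samples are excluded.
#' @export
rna_slopes <- function(tpm, areas, gene_subset = NULL, tpm_floor = 1,
                       intercept = TRUE) {
  tpm <- as.matrix(tpm)
  if (ncol(tpm) != length(areas)) stop("areas must match the sample columns")
  if (!is.null(gene_subset)) {
    tpm <- tpm[rownames(tpm) %in% gene_subset, , drop = FALSE]
    tpm <- sweep(tpm, 2, colSums(tpm), "/") * 1e6
  }
  tpm[tpm < tpm_floor] <- NA
  x <- areas / mean(areas)
  rows <- lapply(rownames(tpm), function(g) {
    v <- tpm[g, ]
    ok <- !is.na(v)
    if (sum(ok) < 2) return(NULL)
    y <- v / mean(v, na.rm = TRUE)
    data.frame(gene_id = g, slope = .log2_slope(y[ok], x[ok], intercept),
               n_samples = sum(ok))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Circular distance from oriC
#'
#' Distance in base pairs between a gene midpoint and the origin of
#' replication on the circular chromosome:
#' `min(|m - oric|, |m - L - oric|, |m + L - oric|)`. Defaults are the
#' E. coli K-12 MG1655 values (oriC at bp 3,925,859 of 4,641,652).
#'
#' @param midpoint gene midpoint coordinates, bp (1-based; vectorized).
#' @param oric oriC coordinate, bp.
#' @param genome_length chromosome length, bp.
#' @return circular distances, bp.
#' @export
oric_distance <- function(midpoint, oric = 3925859, genome_length = 4641652) {
  if (any(midpoint < 1 | midpoint > genome_length))
    stop("midpoint outside [1, genome_length]")
  pmin(abs(midpoint - oric),
       abs(midpoint - genome_length - oric),
       abs(midpoint + genome_length - oric))
}

#' PCA summary of a relative-concentration matrix
#'
#' Principal components of the entities x samples relative-concentration
#' matrix (samples as observations, centered, unscaled). Reports the fraction
#' of total variance explained by PC1 and the sample projections, paired with
#' log2-transformed cell areas.
#'
#' @param mat numeric matrix, entities x samples (complete cases used).
#' @param areas cell area per sample, um^2.
#' @return list: pc1_var_fraction, projections (data.frame: sample, pc1,
#'   log2_area).
#' @export
pca_summary <- function(mat, areas) {
  mat <- as.matrix(mat)
  if (ncol(mat) != length(areas)) stop("areas must match the sample columns")
  mat <- mat[stats::complete.cases(mat), , drop = FALSE]
  pc <- stats::prcomp(t(mat), center = TRUE, scale. = FALSE)
  tot <- sum(pc$sdev^2)
  frac <- if (tot > 0) pc$sdev[1]^2 / tot else 1
  list(pc1_var_fraction = frac,
       projections = data.frame(
         sample = colnames(mat) %||% seq_len(ncol(mat)),
         pc1 = pc$x[, 1], log2_area = log2(areas)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Compare scaling slopes between a gene set and its complement
#'
#' Two-sided Mann-Whitney (Wilcoxon rank-sum) test of the slopes of genes in
#' `gene_set` against all remaining genes, with per-group medians and
#' inter-quartile ranges. Duplicated ids are de-duplicated.
#'
#' @param slopes data.frame with columns for ids (first column or
#'   `id_col`) and `slope`.
#' @param gene_set character vector of ids (e.g. essential genes).
#' @param id_col name of the id column. Default the first column.
#' @return list: p_value, statistic, n_in, n_out, median_in, median_out,
#'   iqr_in, iqr_out.
#' @export
gene_set_compare <- function(slopes, gene_set, id_col = names(slopes)[1]) {
  slopes <- slopes[!duplicated(slopes[[id_col]]), , drop = FALSE]
  gene_set <- unique(gene_set)
  inset <- slopes[[id_col]] %in% gene_set
  if (!any(inset) || all(inset)) stop("both groups must be non-empty")
  a <- slopes$slope[inset]; b <- slopes$slope[!inset]
  wt <- stats::wilcox.test(a, b, alternative = "two.sided", exact = FALSE)
  list(p_value = wt$p.value, statistic = unname(wt$statistic),
       n_in = length(a), n_out = length(b),
       median_in = stats::median(a), median_out = stats::median(b),
       iqr_in = stats::IQR(a), iqr_out = stats::IQR(b))
}

#' Correlate scaling slopes with a gene-level covariate
#'
#' Spearman correlation between slopes and a covariate on an optional subset
#' (e.g. genes with mRNA decay rate above 0.7/min), plus equal-count bins of
#' the covariate with mean and standard error of the slopes.
#'
#' @param slopes data.frame: id column + slope.
#' @param covariate data.frame: id column + value.
#' @param subset_rule optional predicate on the covariate values, e.g.
#'   `function(v) v > 0.7`.
#' @param n_bins number of equal-count bins. Default 8.
#' @param id_col id column name shared by both tables.
#' @return list: rho, p_value, n, unreliable (TRUE when n < 10), binned
#'   (data.frame: bin, covariate_mean, slope_mean, slope_sem, n).
#' @export
correlate_covariate <- function(slopes, covariate, subset_rule = NULL,
                                n_bins = 8, id_col = names(slopes)[1]) {
  merged <- merge(slopes[, c(id_col, "slope")],
                  stats::setNames(covariate[, 1:2], c(id_col, "value")),
                  by = id_col)
  if (!is.null(subset_rule)) merged <- merged[subset_rule(merged$value), ,
                                              drop = FALSE]
  n <- nrow(merged)
  if (n < 3) stop("subset too small to correlate")
  ct <- suppressWarnings(stats::cor.test(merged$slope, merged$value,
                                         method = "spearman"))
  qs <- stats::quantile(merged$value, probs = seq(0, 1, length.out = n_bins + 1))
  bin <- cut(merged$value, unique(qs), include.lowest = TRUE, labels = FALSE)
  binned <- do.call(rbind, lapply(sort(unique(bin)), function(b) {
    s <- merged$slope[bin == b]
    data.frame(bin = b, covariate_mean = mean(merged$value[bin == b]),
               slope_mean = mean(s),
               slope_sem = stats::sd(s) / sqrt(length(s)), n = length(s))
  }))
  list(rho = unname(ct$estimate), p_value = ct$p.value, n = n,
       unreliable = n < 10, binned = binned)
}

#' MS1-based relative protein abundance
#'
#' Summed peptide ion intensity per protein divided by the protein's amino
#' acid sequence length (larger proteins produce more tryptic peptides).
#'
#' @param intensities data.frame: protein_id, intensity (one row per peptide
#'   ion).
#' @param lengths data.frame: protein_id, length (residues, > 0).
#' @return data.frame: protein_id, abundance. Proteins without a length are
#'   skipped.
#' @export
ms1_abundance <- function(intensities, lengths) {
  if (any(lengths$length <= 0)) stop("length must be > 0")
  tot <- stats::aggregate(intensity ~ protein_id, intensities, sum)
  merged <- merge(tot, lengths, by = "protein_id")
  data.frame(protein_id = merged$protein_id,
             abundance = merged$intensity / merged$length)
}

#' Census of near-zero scaling slopes
#'
#' Counts entities whose slope lies strictly inside (-band, band) — i.e.
#' whose relative concentration changes by less than 2^band-fold per cell
#' size doubling.
#'
#' @param slopes numeric slopes or a data.frame with a `slope` column.
#' @param band half-width of the near-zero band. Default 0.2.
#' @return list: n_within, n_total, fraction.
#' @export
slope_census <- function(slopes, band = 0.2) {
  if (is.data.frame(slopes)) slopes <- slopes$slope
  slopes <- slopes[is.finite(slopes)]
  list(n_within = sum(slopes > -band & slopes < band),
       n_total = length(slopes),
       fraction = mean(slopes > -band & slopes < band))
}
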