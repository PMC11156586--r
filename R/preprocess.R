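#' Intensity-based probe filter
#'
#' Drops microarray probes that do not exceed background noise in at least
#' `min_fraction` of samples, with the fraction computed over all samples
#' pooled across donors (a probe must clear the bar cohort-wide, not per
#' donor).  Donors without probe-level data pass through untouched.
#'
#' @param donors list of [donor_expression()] with probe payloads.
#' @param min_fraction minimum above-background fraction (default 0.5).
#' @return The donor list with filtered probe sets.
#' @export
filter_probes_by_intensity <- function(donors, min_fraction = 0.5) {
  with_probes <- vapply(donors, function(d) !is.null(d$probes), logical(1))
  if (!any(with_probes)) return(donors)
  probe_ids <- rownames(donors[[which(with_probes)[1]]]$probes$values)
  above <- integer(length(probe_ids)); total <- integer(length(probe_ids))
  names(above) <- names(total) <- probe_ids
  for (d in donors[with_probes]) {
    ab <- d$probes$above_background[probe_ids, , drop = FALSE]
    above <- above + rowSums(ab)
    total <- total + ncol(ab)
  }
  keep <- probe_ids[above / total >= min_fraction]
  if (length(keep) == 0L) stop_empty("no probes survive the intensity filter")
  lapply(donors, function(d) {
    if (is.null(d$probes)) return(d)
    d$probes$values <- d$probes$values[keep, , drop = FALSE]
    d$probes$probe_gene <- d$probes$probe_gene[keep]
    d$probes$above_background <- d$probes$above_background[keep, , drop = FALSE]
    d
  })
}

# collapse a donor's probe x sample matrix to probe x region (mean of samples
# per region)
probe_region_matrix <- function(donor) {
  pv <- donor$probes$values
  reg <- donor$probes$sample_region[colnames(pv)]
  regs <- unique(reg)
  out <- vapply(regs, function(r)
    rowMeans(pv[, reg == r, drop = FALSE]), numeric(nrow(pv)))
  colnames(out) <- regs
  out
}

#' Aggregate probes to genes by cross-donor stability
#'
#' For every gene with multiple probes, selects the single probe whose
#' regional profile has the highest mean Pearson correlation across donor
#' pairs (computed on each pair's shared regions); single-probe genes pass
#' through.  Ties are broken by lowest probe id.  Returns gene-level donors
#' (region x gene matrices).
#'
#' @param donors list of [donor_expression()] with probe payloads (>= 2
#'   donors required for the correlation criterion).
#' @return Donor list with gene-level `values`; probe payloads dropped.
#' @export
aggregate_probes_to_genes <- function(donors) {
  with_probes <- vapply(donors, function(d) !is.null(d$probes), logical(1))
  if (!any(with_probes)) return(donors)
  if (sum(with_probes) < 2L)
    stop_invalid("probe aggregation needs >= 2 donors with probe data")
  pr <- lapply(donors[with_probes], probe_region_matrix)
  probe_gene <- donors[[which(with_probes)[1]]]$probes$probe_gene
  probe_ids <- names(probe_gene)
  # mean across donor pairs of per-probe regional correlation
  pair_idx <- combn(length(pr), 2)
  rsum <- numeric(length(probe_ids)); rcnt <- numeric(length(probe_ids))
  for (p in seq_len(ncol(pair_idx))) {
    a <- pr[[pair_idx[1, p]]]; b <- pr[[pair_idx[2, p]]]
    shared <- intersect(colnames(a), colnames(b))
    if (length(shared) < 3L) next
    r <- colwise_cor(t(a[probe_ids, shared, drop = FALSE]),
                     t(b[probe_ids, shared, drop = FALSE]))
    ok <- is.finite(r)
    rsum[ok] <- rsum[ok] + r[ok]
    rcnt[ok] <- rcnt[ok] + 1
  }
  mean_r <- ifelse(rcnt > 0, rsum / rcnt, -Inf)
  names(mean_r) <- probe_ids
  chosen <- vapply(split(probe_ids, probe_gene[probe_ids]), function(ids) {
    if (length(ids) == 1L) return(ids)
    best <- mean_r[ids]
    if (all(!is.finite(best))) {
      warning("gene ", probe_gene[ids[1]],
              ": no defined probe correlations; keeping lowest probe id")
      return(sort(ids)[1])
    }
    sort(ids[best == max(best)])[1]  # tie -> lowest probe id
  }, character(1))
  lapply(donors, function(d) {
    if (is.null(d$probes)) return(d)
    prm <- probe_region_matrix(d)
    vals <- t(prm[chosen, , drop = FALSE])
    colnames(vals) <- names(chosen)
    vals <- vals[, order(colnames(vals)), drop = FALSE]
    donor_expression(d$donor_id, vals, d$all_regions, probes = NULL)
  })
}

#' Scaled robust sigmoid normalization
#'
#' Outlier-robust mapping of a numeric vector into [0, 1]:
#' `y = 1 / (1 + exp(-(x - median) / (IQR / 1.35)))`, then min-max rescaled.
#' IQR uses linear-interpolation quantiles (R type 7).  Rank order is
#' preserved; a zero-IQR (effectively constant) input maps to all 0.5.
#'
#' @param x numeric vector, length >= 2.
#' @return numeric vector in [0, 1].
#' @examples
#' srs_normalize(c(0, 1, 2))   # 0, 0.5, 1
#' @export
srs_normalize <- function(x) {
  if (length(x) < 2L) stop_invalid("srs_normalize needs length >= 2")
  iqr <- diff(quantile(x, c(0.25, 0.75), names = FALSE))
  if (iqr == 0) return(rep(0.5, length(x)))
  y <- 1 / (1 + exp(-(x - median(x)) / (iqr / 1.35)))
  (y - min(y)) / (max(y) - min(y))
}

# SRS-normalize a donor matrix: per sample (row) across genes, then per gene
# (column) across samples
srs_normalize_donor <- function(values) {
  values <- t(apply(values, 1, srs_normalize))
  apply(values, 2, srs_normalize)
}

#' Differential stability of genes across donors
#'
#' For each gene, the mean over donor pairs of the Pearson correlation of the
#' gene's regional expression profile between the two donors, computed on the
#' pair's shared regions.  Pairs where the correlation is undefined (a donor
#' constant for that gene) are excluded from the mean.
#'
#' @param donors list of gene-level [donor_expression()] (>= 2).
#' @param min_shared_regions minimum shared regions for a pair to contribute.
#' @return Named numeric vector of per-gene DS values in [-1, 1]; class
#'   `differential_stability`.
#' @export
differential_stability <- function(donors, min_shared_regions = 3L) {
  if (length(donors) < 2L) stop_invalid("differential stability needs >= 2 donors")
  genes <- colnames(donors[[1]]$values)
  pair_idx <- combn(length(donors), 2)
  rsum <- numeric(length(genes)); rcnt <- numeric(length(genes))
  dropped <- 0L
  for (p in seq_len(ncol(pair_idx))) {
    a <- donors[[pair_idx[1, p]]]; b <- donors[[pair_idx[2, p]]]
    shared <- intersect(rownames(a$values), rownames(b$values))
    if (length(shared) < min_shared_regions)
      stop_invalid("donor pair shares fewer than ", min_shared_regions, " regions")
    r <- colwise_cor(a$values[shared, genes, drop = FALSE],
                     b$values[shared, genes, drop = FALSE])
    # constant gene within a donor -> colwise_cor returns 0 via zscore; detect
    sda <- apply(a$values[shared, genes, drop = FALSE], 2, sd)
    sdb <- apply(b$values[shared, genes, drop = FALSE], 2, sd)
    ok <- sda > 0 & sdb > 0
    dropped <- dropped + sum(!ok)
    rsum[ok] <- rsum[ok] + r[ok]
    rcnt[ok] <- rcnt[ok] + 1
  }
  if (dropped > 0L)
    warning(dropped, " gene-pair correlations undefined (constant profile); ",
            "excluded from the pair mean")
  ds <- ifelse(rcnt > 0, rsum / rcnt, NA_real_)
  structure(setNames(ds, genes), class = "differential_stability")
}

#' Retain the most differentially stable genes
#'
#' Keeps the `ceiling(retain_fraction * G)` genes with highest differential
#' stability; ties at the cut are broken by gene id ascending.
#'
#' @param ds a [differential_stability()] vector.
#' @param retain_fraction fraction of genes to keep, in (0, 1].
#' @return Character vector of retained gene ids (original gene order).
#' @export
filter_genes_by_ds <- function(ds, retain_fraction = 0.5) {
  if (retain_fraction <= 0 || retain_fraction > 1)
    stop_invalid("retain_fraction must be in (0, 1]")
  genes <- names(ds)
  n_keep <- ceiling(retain_fraction * length(ds))
  ord <- order(-ds, genes)  # DS desc, then gene id asc for ties
  keep <- genes[ord[seq_len(n_keep)]]
  genes[genes %in% keep]
}

#' Filter regions by donor coverage
#'
#' Keeps regions sampled (non-missing) in at least `min_donors` donors.
#'
#' @param donors list of [donor_expression()].
#' @param min_donors minimum number of donors a region must be present in.
#' @return Character vector of retained region ids (atlas order).
#' @export
filter_regions_by_coverage <- function(donors, min_donors = 3L) {
  if (min_donors < 1L || min_donors > length(donors))
    stop_invalid("min_donors must be between 1 and the number of donors")
  all_regions <- donors[[1]]$all_regions
  counts <- rowSums(vapply(donors, function(d)
    all_regions %in% rownames(d$values), logical(length(all_regions))))
  keep <- all_regions[counts >= min_donors]
  if (length(keep) == 0L) stop_empty("no region sampled in >= ", min_donors, " donors")
  keep
}

#' Assemble the donor-averaged region x gene matrix
#'
#' Within each donor, samples are normalized across genes then genes across
#' samples (both by [srs_normalize()]); the normalized matrices are then
#' averaged across donors per region, ignoring each donor's missing regions.
#'
#' @param donors list of gene-level [donor_expression()].
#' @param genes gene subset to keep (e.g. from [filter_genes_by_ds()]).
#' @param regions region subset to keep (e.g. from
#'   [filter_regions_by_coverage()]).
#' @param normalize apply SRS normalization per donor (default TRUE).
#' @return A `region_gene_matrix`: numeric matrix (regions x genes) with a
#'   `provenance` attribute recording the filters applied.
#' @export
assemble_group_matrix <- function(donors, genes = NULL, regions = NULL,
                                  normalize = TRUE) {
  genes <- genes %||% colnames(donors[[1]]$values)
  regions <- regions %||% donors[[1]]$all_regions
  acc <- matrix(0, length(regions), length(genes),
                dimnames = list(regions, genes))
  cnt <- matrix(0L, length(regions), length(genes))
  for (d in donors) {
    vals <- d$values[, genes, drop = FALSE]
    if (normalize) vals <- srs_normalize_donor(vals)
    present <- intersect(regions, rownames(vals))
    idx <- match(present, regions)
    acc[idx, ] <- acc[idx, ] + vals[present, , drop = FALSE]
    cnt[idx, ] <- cnt[idx, ] + 1L
  }
  if (any(cnt == 0L))
    stop_invalid("some region x gene cells are covered by no donor; ",
                 "tighten the region filter")
  out <- acc / cnt
  structure(out, class = c("region_gene_matrix", class(out)),
            provenance = list(n_donors = length(donors),
                              n_genes = length(genes),
                              n_regions = length(regions),
                              normalized = normalize))
}

#' Run the full preprocessing chain on a cohort
#'
#' Probe intensity filter and probe aggregation (if probe-level), donor
#' coverage region filter, SRS normalization, differential-stability gene
#' filter, and donor averaging.
#'
#' @param donors list of [donor_expression()] (a `synthetic_cohort$donors`
#'   or read from disk).
#' @param ds_fraction differential-stability retain fraction.
#' @param min_donors donor-coverage threshold for regions.
#' @param intensity_fraction probe intensity threshold (probe-level only).
#' @return A `region_gene_matrix` (see [assemble_group_matrix()]).
#' @export
preprocess_cohort <- function(donors, ds_fraction = 0.5, min_donors = 3L,
                              intensity_fraction = 0.5) {
  donors <- filter_probes_by_intensity(donors, intensity_fraction)
  donors <- aggregate_probes_to_genes(donors)
  regions <- filter_regions_by_coverage(donors, min_donors)
  ds <- differential_stability(donors)
  genes <- filter_genes_by_ds(ds, ds_fraction)
  m <- assemble_group_matrix(donors, genes, regions)
  attr(m, "provenance") <- c(attr(m, "provenance"),
                             list(ds_fraction = ds_fraction,
                                  min_donors = min_donors,
                                  intensity_fraction = intensity_fraction))
  m
}
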