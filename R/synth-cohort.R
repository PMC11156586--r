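#' Synthetic ground truth for a multi-donor cohort
#'
#' Holds the latent spatial components, gene loadings and noise settings used
#' to generate a synthetic cohort, so downstream stages can be scored against
#' known truth.  Latent score columns are centered, mutually orthogonal and
#' z-scored; loadings are standard normal draws; per-component amplitude is
#' `snr * noise_sd` so the configured SNR is the elementwise signal/noise sd
#' ratio of each component's contribution.
#'
#' @name synthetic_truth
#' @keywords internal
NULL

new_synthetic_truth <- function(latent_scores, loadings, snr, noise_sd,
                                donor_offset_sd, missing_frac,
                                gene_noise_factor, smoothness,
                                age_amplitude = NULL) {
  structure(list(latent_scores = latent_scores, loadings = loadings,
                 component_snr = snr, amplitude = snr * noise_sd,
                 noise_sd = noise_sd, donor_offset_sd = donor_offset_sd,
                 missing_frac = missing_frac,
                 gene_noise_factor = gene_noise_factor,
                 smoothness = smoothness, age_amplitude = age_amplitude),
            class = "synthetic_truth")
}

#' Single-donor expression container
#'
#' Region-level values are a region x gene matrix restricted to the donor's
#' sampled (non-missing) regions.  Probe-level donors additionally carry a
#' probe x sample matrix, probe-to-gene and sample-to-region maps, and
#' above-background flags, and are reduced to gene level by
#' [filter_probes_by_intensity()] and [aggregate_probes_to_genes()].
#'
#' @param donor_id donor identifier.
#' @param values region x gene numeric matrix (row names = sampled regions).
#' @param all_regions character vector of every atlas region (defines the
#'   missing mask).
#' @param probes optional probe-level payload (list with `values`,
#'   `probe_gene`, `sample_region`, `above_background`).
#' @return An object of class `donor_expression`.
#' @export
donor_expression <- function(donor_id, values, all_regions, probes = NULL) {
  if (!is.matrix(values)) stop_invalid("values must be a matrix")
  if (nrow(values) == 0L) stop_invalid("donor ", donor_id, " has no sampled regions")
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop_invalid("values needs region row names and gene column names")
  if (!all(rownames(values) %in% all_regions))
    stop_invalid("donor regions must be a subset of the atlas parcels")
  if (anyDuplicated(colnames(values))) stop_invalid("gene ids must be unique")
  structure(list(donor_id = donor_id, values = values,
                 missing = setdiff(all_regions, rownames(values)),
                 all_regions = all_regions, probes = probes),
            class = "donor_expression")
}

#' @export
print.donor_expression <- function(x, ...) {
  cat("<donor_expression> ", x$donor_id, ": ", nrow(x$values), " regions x ",
      ncol(x$values), " genes (", length(x$missing), " missing regions",
      if (!is.null(x$probes)) "; probe-level data attached", ")\n", sep = "")
  invisible(x)
}

# upper Cholesky factor of the sphere GP covariance exp(-d / ell)
gp_chol <- function(coords, ell) {
  n <- nrow(coords)
  chol(exp(-greatcircle_dist(coords) / ell) + diag(1e-8, n))
}

# k z-scored smooth Gaussian-field maps on the sphere
draw_gp_fields <- function(ch, k) {
  raw <- t(ch) %*% matrix(rnorm(nrow(ch) * k), nrow(ch), k)
  apply(raw, 2, zscore)
}

# Draw K smooth Gaussian-field maps on the sphere (cov exp(-d / ell)), then
# Gram-Schmidt against the constant vector and each other, and z-score.
draw_latent_maps <- function(coords, k, ell) {
  n <- nrow(coords)
  ch <- gp_chol(coords, ell)
  raw <- t(ch) %*% matrix(rnorm(n * k), n, k)
  out <- matrix(0, n, k)
  for (j in seq_len(k)) {
    v <- raw[, j] - mean(raw[, j])
    if (j > 1L) for (m in seq_len(j - 1L))
      v <- v - sum(v * out[, m]) / sum(out[, m]^2) * out[, m]
    v <- v - mean(v)
    out[, j] <- v
  }
  out <- apply(out, 2, zscore)
  rownames(out) <- rownames(coords)
  colnames(out) <- paste0("L", seq_len(k))
  out
}

#' Generate a synthetic multi-donor cortical expression cohort
#'
#' Each donor's region x gene matrix is the shared latent signal
#' `sum_k amplitude_k * latent_k %*% t(loading_k)` plus three kinds of
#' donor-specific variation: a per-donor per-gene offset (between-donor
#' batch structure), donor-individual smooth spatial fields with their own
#' gene loadings (individual expression gradients, the kind of structure
#' that caps cross-donor reproducibility of higher-order components in real
#' atlases), and i.i.d. measurement noise whose sd can be inflated for a
#' random subset of "noisy" genes (what the differential-stability filter
#' is meant to remove).  The per-component `snr` is defined against the
#' total unshared (donor-specific smooth + i.i.d.) variation, so the
#' component amplitude is `snr * sqrt(noise_sd^2 + n_nuisance *
#' nuisance_sd^2)`.  Each donor then drops parcels independently at
#' `missing_frac`.  Optionally each gene is expanded into 1-3 probes with
#' probe-level noise and above-background flags, to exercise the intensity
#' filter and probe-aggregation steps.
#'
#' @param atlas a [parcel_atlas()].
#' @param n_donors number of donors (>= 2).
#' @param n_genes number of genes.
#' @param snr per-component signal-to-noise ratios (signal sd / noise sd);
#'   length K. K must be at most `min(n_parcels, n_genes) / 4`.
#' @param ell smoothness length of the latent Gaussian fields, radians.
#' @param noise_sd sd of the i.i.d. measurement noise (baseline genes).
#' @param n_nuisance number of donor-individual smooth spatial fields per
#'   donor (default 3; 0 disables them).
#' @param nuisance_sd loading sd of the donor-individual fields; default
#'   `8 * noise_sd`, which puts the median inter-donor differential
#'   stability of generated genes near 0.25-0.3, the regime reported for
#'   real multi-donor atlases (donor-level biological structure dominates
#'   measurement noise).
#' @param donor_offset_sd sd of the per-donor per-gene offset; default
#'   `0.2 * sqrt(sum(amplitude^2))` (20% of the total signal sd).
#' @param missing_frac per-donor probability that a parcel is unsampled.
#' @param prop_noisy_genes fraction of genes whose noise sd is multiplied by
#'   `noisy_gene_factor`.
#' @param noisy_gene_factor noise inflation for the noisy gene subset.
#' @param probe_expansion expand genes into probes (default off).
#' @param background_probe_frac fraction of probes that are background-like
#'   (rarely exceed background noise) when `probe_expansion = TRUE`.
#' @param seed integer seed; generation is deterministic given it.
#' @return An object of class `synthetic_cohort`: list with `donors` (list of
#'   [donor_expression()]), `truth` (the `synthetic_truth`) and `atlas`.
#' @examples
#' atl <- generate_atlas(60, seed = 1)
#' coh <- generate_cohort(atl, n_donors = 4, n_genes = 200, snr = c(6, 3),
#'                        seed = 2)
#' coh$donors[[1]]
#' @export
generate_cohort <- function(atlas, n_donors, n_genes, snr = c(8, 4, 2),
                            ell = 0.5, noise_sd = 1, n_nuisance = 3L,
                            nuisance_sd = NULL, donor_offset_sd = NULL,
                            missing_frac = 0.25, prop_noisy_genes = 0,
                            noisy_gene_factor = 5, probe_expansion = FALSE,
                            background_probe_frac = 0.2, seed = 1L) {
  if (n_donors < 2L) stop_invalid("need at least 2 donors")
  k <- length(snr)
  if (k < 1L || any(snr <= 0)) stop_invalid("snr must be positive, length >= 1")
  n_parcels <- nrow(atlas)
  if (k > min(n_parcels, n_genes) / 4)
    stop_invalid("K = ", k, " infeasible for ", n_parcels, " parcels x ",
                 n_genes, " genes (need K <= min/4)")
  nuisance_sd <- nuisance_sd %||% (8 * noise_sd)
  with_seed(seed, {
    coords <- atlas_coords(atlas)
    latent <- draw_latent_maps(coords, k, ell)
    genes <- sprintf("G%05d", seq_len(n_genes))
    loadings <- matrix(rnorm(n_genes * k), n_genes, k,
                       dimnames = list(genes, paste0("L", seq_len(k))))
    # with noise_sd = 0 (noise-free limit) snr is read as absolute amplitude
    amplitude <- snr * (if (noise_sd > 0) noise_sd else 1)
    signal <- latent %*% (t(loadings) * amplitude)
    colnames(signal) <- genes
    gene_factor <- rep(1, n_genes)
    if (prop_noisy_genes > 0) {
      noisy <- sample.int(n_genes, round(prop_noisy_genes * n_genes))
      gene_factor[noisy] <- noisy_gene_factor
    }
    if (is.null(donor_offset_sd))
      donor_offset_sd <- 0.2 * sqrt(sum(amplitude^2))
    truth <- new_synthetic_truth(latent, loadings, snr, noise_sd,
                                 donor_offset_sd, missing_frac, gene_factor, ell)
    truth$n_nuisance <- n_nuisance
    truth$nuisance_sd <- nuisance_sd
    ch <- if (n_nuisance > 0L) gp_chol(coords, ell) else NULL
    # one probe design shared by every donor: the probe -> gene map and the
    # per-probe quality (background-like or not) are properties of the array
    probe_design <- NULL
    if (probe_expansion) {
      nprobe <- sample(1:3, n_genes, replace = TRUE)
      probe_gene <- rep(genes, nprobe)
      probe_id <- paste0(probe_gene, "_p", unlist(lapply(nprobe, seq_len)))
      is_bg <- runif(length(probe_id)) < background_probe_frac
      probe_design <- list(probe_id = probe_id,
                           probe_gene = setNames(probe_gene, probe_id),
                           p_above = ifelse(is_bg, 0.2, 0.9))
    }
    donors <- vector("list", n_donors)
    for (d in seq_len(n_donors)) {
      noise <- matrix(rnorm(n_parcels * n_genes), n_parcels, n_genes)
      noise <- sweep(noise, 2, noise_sd * gene_factor, "*")
      offs <- rnorm(n_genes, 0, donor_offset_sd)
      vals <- signal + noise + matrix(offs, n_parcels, n_genes, byrow = TRUE)
      if (n_nuisance > 0L && nuisance_sd > 0) {
        fields <- draw_gp_fields(ch, n_nuisance)
        bload <- matrix(rnorm(n_genes * n_nuisance, 0, nuisance_sd),
                        n_genes, n_nuisance)
        vals <- vals + fields %*% t(bload)
      }
      rownames(vals) <- atlas$parcel_id
      keep <- rbinom(n_parcels, 1, 1 - missing_frac) == 1
      if (sum(keep) < max(10L, k + 2L))
        keep[sample.int(n_parcels, max(10L, k + 2L))] <- TRUE
      vals <- vals[keep, , drop = FALSE]
      probes <- if (probe_expansion)
        expand_probes(vals, probe_design, noise_sd) else NULL
      donors[[d]] <- donor_expression(sprintf("donor%02d", d), vals,
                                      atlas$parcel_id, probes)
    }
    structure(list(donors = donors, truth = truth, atlas = atlas),
              class = "synthetic_cohort")
  })
}

# probe-level expansion: each probe = its gene's signal + probe noise; one
# sample per sampled region; background-like probes rarely exceed noise
expand_probes <- function(region_vals, design, noise_sd) {
  samples <- paste0("S_", rownames(region_vals))
  pv <- region_vals[, design$probe_gene, drop = FALSE] +
    matrix(rnorm(nrow(region_vals) * length(design$probe_id),
                 0, 0.5 * max(noise_sd, 1e-3)),
           nrow(region_vals))
  pv <- t(pv)  # probe x sample
  rownames(pv) <- design$probe_id
  colnames(pv) <- samples
  above <- matrix(runif(length(pv)) < design$p_above[row(pv)], nrow(pv),
                  dimnames = dimnames(pv))
  list(values = pv,
       probe_gene = design$probe_gene,
       sample_region = setNames(rownames(region_vals), samples),
       above_background = above)
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat("<synthetic_cohort> ", length(x$donors), " donors, ",
      nrow(x$atlas), " parcels, ", nrow(x$truth$loadings), " genes, K = ",
      ncol(x$truth$latent_scores), " (snr ",
      paste(signif(x$truth$component_snr, 3), collapse = "/"), ")\n", sep = "")
  invisible(x)
}

#' Attach age-amplitude functions to a synthetic truth
#'
#' Each component's contribution to developmental expression is modulated by
#' an amplitude function of age (years).  Convenience constructors:
#' `age_amp_constant(a)` and `age_amp_logistic(low, high, midpoint, rate)`
#' (a logistic rise in years).
#'
#' @param truth a `synthetic_truth`.
#' @param funs list of K functions of age in years.
#' @return The truth with `age_amplitude` set.
#' @export
set_age_amplitude <- function(truth, funs) {
  if (length(funs) != ncol(truth$latent_scores))
    stop_invalid("need one amplitude function per component")
  truth$age_amplitude <- funs
  truth
}

#' @rdname set_age_amplitude
#' @param a constant amplitude.
#' @export
age_amp_constant <- function(a) { force(a); function(age) rep(a, length(age)) }

#' @rdname set_age_amplitude
#' @param low,high asymptotic amplitudes before/after the rise.
#' @param midpoint age (years) of half-rise.
#' @param rate logistic steepness (1/years).
#' @export
age_amp_logistic <- function(low, high, midpoint, rate = 1) {
  force(low); force(high); force(midpoint); force(rate)
  function(age) low + (high - low) / (1 + exp(-rate * (age - midpoint)))
}
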