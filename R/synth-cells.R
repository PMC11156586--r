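#' Generate synthetic single-cell expression with latent component coupling
#'
#' Emulates single-nucleus RNA-seq structure: each cell has a type with a
#' type-specific per-gene baseline, plus a per-cell latent activation
#' `t_jk ~ N(0, 1)` of every truth component so that genes with positive and
#' negative loadings on the same component anti-covary within each cell type,
#' plus i.i.d. noise.
#'
#' @param truth a `synthetic_truth` (supplies gene loadings).
#' @param n_cells number of cells.
#' @param cell_types named numeric vector of type proportions (must sum to 1).
#' @param coupling_sd scalar or per-component sd scaling of the latent
#'   activations (0 switches the coupling off).
#' @param baseline_sd sd of type-specific per-gene baselines.
#' @param noise_sd sd of cell-level noise.
#' @param seed integer seed.
#' @return List of class `synthetic_cells`: `values` (cell x gene matrix),
#'   `cell_type` (factor), `latent` (cell x K activations).
#' @examples
#' atl <- generate_atlas(40, seed = 1)
#' coh <- generate_cohort(atl, 2, 100, snr = c(5, 3), seed = 1)
#' cells <- generate_single_cells(coh$truth, 200,
#'   c(neuron = 0.6, glia = 0.4), seed = 3)
#' table(cells$cell_type)
#' @export
generate_single_cells <- function(truth, n_cells,
                                  cell_types = c(neuron = 0.5, glia = 0.5),
                                  coupling_sd = 1, baseline_sd = 2,
                                  noise_sd = 1, seed = 1L) {
  if (length(cell_types) == 0L) stop_invalid("cell_types must be non-empty")
  if (is.null(names(cell_types)) || any(!nzchar(names(cell_types))))
    stop_invalid("cell_types must be named")
  if (abs(sum(cell_types) - 1) > 1e-8) stop_invalid("type proportions must sum to 1")
  k <- ncol(truth$loadings)
  coupling_sd <- rep_len(coupling_sd, k)
  with_seed(seed, {
    genes <- rownames(truth$loadings)
    types <- sample(names(cell_types), n_cells, replace = TRUE,
                    prob = cell_types)
    base <- matrix(rnorm(length(cell_types) * length(genes), 0, baseline_sd),
                   length(cell_types), length(genes),
                   dimnames = list(names(cell_types), genes))
    tlat <- matrix(rnorm(n_cells * k), n_cells, k)
    vals <- base[types, , drop = FALSE] +
      (tlat * rep(coupling_sd, each = n_cells)) %*% t(truth$loadings) +
      matrix(rnorm(n_cells * length(genes), 0, noise_sd), n_cells)
    rownames(vals) <- sprintf("cell%05d", seq_len(n_cells))
    structure(list(values = vals, cell_type = factor(types), latent = tlat),
              class = "synthetic_cells")
  })
}

# years -> post-conception days; error for impossible (pre-conception) ages
age_to_pcd <- function(age_years, gestation_days = 280) {
  days <- 365.25 * age_years + gestation_days
  if (any(days <= 0))
    stop_invalid("age corresponds to <= 0 post-conception days")
  days
}

#' Generate synthetic developmental expression
#'
#' Emulates an age-resolved regional RNA-seq atlas: one donor per requested
#' age, a random sex per donor, and expression
#' `sum_k amplitude_k(age) * (latent_k(region) + program_mean) *
#' loading_k(gene) + noise`, where the per-component amplitude functions
#' live on the truth (see [set_age_amplitude()]).  `program_mean` is the
#' region-constant expression level of each program, so a rising amplitude
#' raises the absolute expression of its positively loaded genes in every
#' region, on top of the spatial patterning carried by the (z-scored)
#' latent map.  Ages are years relative to birth (negative = fetal) and are
#' converted to post-conception days internally as `365.25 * years + 280`.
#'
#' @param truth a `synthetic_truth` with `age_amplitude` set.
#' @param ages donor ages in years, each within [-0.75, 40].
#' @param regions subset of truth regions to sample (default all).
#' @param program_mean region-constant level added to each latent map
#'   (default 1).
#' @param noise_sd observation noise sd.
#' @param seed integer seed.
#' @return Long-format data frame: donor, age_years, sex, region, gene, value.
#' @export
generate_development <- function(truth, ages, regions = NULL,
                                 program_mean = 1, noise_sd = 1, seed = 1L) {
  if (is.null(truth$age_amplitude))
    stop_invalid("truth has no age_amplitude; see set_age_amplitude()")
  if (any(ages < -0.75 | ages > 40))
    stop_invalid("ages must lie within [-0.75, 40] years")
  age_to_pcd(ages)  # validates the post-conception-day conversion
  latent <- truth$latent_scores
  regions <- regions %||% rownames(latent)
  latent <- latent[regions, , drop = FALSE]
  genes <- rownames(truth$loadings)
  k <- ncol(latent)
  with_seed(seed, {
    out <- vector("list", length(ages))
    sexes <- sample(c("M", "F"), length(ages), replace = TRUE)
    for (d in seq_along(ages)) {
      amp <- vapply(seq_len(k),
                    function(j) truth$age_amplitude[[j]](ages[d]), numeric(1))
      vals <- (latent + program_mean) %*% (t(truth$loadings) * amp) +
        matrix(rnorm(length(regions) * length(genes), 0, noise_sd),
               length(regions))
      out[[d]] <- data.frame(
        donor = sprintf("dev%02d", d), age_years = ages[d], sex = sexes[d],
        region = rep(regions, times = length(genes)),
        gene = rep(genes, each = length(regions)),
        value = as.vector(vals), stringsAsFactors = FALSE)
    }
    do.call(rbind, out)
  })
}
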