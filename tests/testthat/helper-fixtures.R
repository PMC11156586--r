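# shared small fixtures, built once per test session

fixture_env <- new.env(parent = emptyenv())

fixture <- function(name, build) {
  if (!exists(name, envir = fixture_env)) assign(name, build(), envir = fixture_env)
  get(name, envir = fixture_env)
}

small_atlas <- function() fixture("atlas60", function() generate_atlas(60, seed = 7))

small_cohort <- function() fixture("cohort60", function()
  generate_cohort(small_atlas(), n_donors = 4, n_genes = 300,
                  snr = c(6, 3), missing_frac = 0.15, seed = 42))

# a random region x gene matrix with dimnames
rand_matrix <- function(r, g, seed = 1) {
  set.seed(seed)
  matrix(rnorm(r * g), r, g,
         dimnames = list(sprintf("R%02d", seq_len(r)),
                         sprintf("G%03d", seq_len(g))))
}

# region-level donor list built directly from matrices (no generator)
donors_from_matrices <- function(mats, all_regions = NULL) {
  all_regions <- all_regions %||% rownames(mats[[1]])
  lapply(seq_along(mats), function(i)
    donor_expression(paste0("d", i), mats[[i]], all_regions))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
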