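# Seeded synthetic-data generators reproducing the statistical structure the
# modelling protocol assumes: a heavily imbalanced binder/non-binder split, a
# small planted subset of class-informative descriptors among many noise
# descriptors, a fraction of constant descriptors to exercise the
# low-information filter, and replicate logRBA measurements with known
# consensus labels.

#' Synthetic dataset configuration
#'
#' Defaults emulate the reference training set: 2462 binders vs 30
#' non-binders (98.8% / 1.2%), 447 descriptors of which 18 carry class
#' signal. Informative descriptors separate the class means by `effect_size`
#' noise standard deviations, with binders drawn at 1.5x the dispersion of
#' non-binders — binders occupy a larger chemical space than non-binders in
#' the data this emulates.
#'
#' @param n_binders,n_nonbinders Class counts (exact, not stochastic).
#' @param n_descriptors Total descriptor count.
#' @param n_informative Number of planted class-informative descriptors.
#' @param effect_size Standardised class-mean separation per informative
#'   descriptor, in units of `noise_sd`.
#' @param noise_sd Standard deviation of the non-binder / noise draws.
#' @param fraction_constant Fraction of descriptors emitted constant, to
#'   exercise [filter_low_information()].
#' @param seed Integer seed; generation is fully reproducible.
#' @return Validated list of class `synth_config`.
#' @export
synth_config <- function(n_binders = 2462L, n_nonbinders = 30L,
                         n_descriptors = 447L, n_informative = 18L,
                         effect_size = 1.5, noise_sd = 1,
                         fraction_constant = 0.1, seed = 1L) {
  stopifnot(n_binders >= 1, n_nonbinders >= 1, n_descriptors >= 1,
            n_informative >= 0, n_informative <= n_descriptors,
            effect_size >= 0, noise_sd > 0,
            fraction_constant >= 0, fraction_constant < 1)
  n_constant <- floor(fraction_constant * n_descriptors)
  if (n_informative + n_constant > n_descriptors)
    stop("n_informative plus constant descriptors exceeds n_descriptors",
         call. = FALSE)
  structure(list(n_binders = as.integer(n_binders),
                 n_nonbinders = as.integer(n_nonbinders),
                 n_descriptors = as.integer(n_descriptors),
                 n_informative = as.integer(n_informative),
                 effect_size = effect_size, noise_sd = noise_sd,
                 fraction_constant = fraction_constant,
                 seed = as.integer(seed)),
            class = "synth_config")
}

#' Generate a synthetic labelled descriptor dataset
#'
#' Binder and non-binder counts match the configuration exactly. Informative
#' descriptors are drawn class-conditionally: non-binders from
#' `N(0, noise_sd)` and binders from a normal with 1.5x the non-binder
#' dispersion whose mean is shifted so that the standardised class-mean
#' separation (mean difference over the pooled standard deviation
#' `sqrt((sd_b^2 + sd_nb^2)/2)`) equals `effect_size` exactly.
#' All other descriptors are class-independent `N(0, noise_sd)` noise, except
#' a `fraction_constant` share emitted constant. Which columns are constant
#' or informative is drawn from the same seeded generator.
#'
#' @param config A [synth_config()].
#' @return List with `dataset` (a [labeled_dataset()], binders first) and
#'   `truth` (list: `informative` descriptor names, `constant` names,
#'   `classes`, and the `config`).
#' @export
generate_dataset <- function(config = synth_config()) {
  stopifnot(inherits(config, "synth_config"))
  set.seed(config$seed)
  n <- config$n_binders + config$n_nonbinders
  p <- config$n_descriptors
  ids <- sprintf("C%05d", seq_len(n))
  nms <- sprintf("D%03d", seq_len(p))
  y <- rep(c(.BINDER, .NONBINDER),
           c(config$n_binders, config$n_nonbinders))
  is_binder <- y == .BINDER
  n_constant <- floor(config$fraction_constant * p)
  special <- sample.int(p, n_constant + config$n_informative)
  constant_cols <- special[seq_len(n_constant)]
  informative_cols <- setdiff(special, constant_cols)
  x <- matrix(stats::rnorm(n * p, 0, config$noise_sd), n, p,
              dimnames = list(ids, nms))
  binder_sd <- 1.5 * config$noise_sd
  # mean shift delivering the configured *standardised* separation
  delta <- config$effect_size *
    sqrt((binder_sd^2 + config$noise_sd^2) / 2)
  for (j in informative_cols) {
    x[is_binder, j] <- stats::rnorm(config$n_binders, delta, binder_sd)
    x[!is_binder, j] <- stats::rnorm(config$n_nonbinders, 0, config$noise_sd)
  }
  for (j in constant_cols)
    x[, j] <- round(stats::runif(1L, -2, 2), 2L)
  list(dataset = labeled_dataset(x, y),
       truth = list(informative = sort(nms[informative_cols]),
                    constant = sort(nms[constant_cols]),
                    classes = stats::setNames(y, ids),
                    config = config))
}

#' Generate replicate logRBA activity records with known consensus labels
#'
#' Each compound receives 1-3 logRBA measurements straddling the binder
#' threshold. The ground-truth consensus label is fixed first and the
#' measurements are then constructed consistently (offsets of known sign
#' from the threshold), so the emitted truth is an independent oracle for
#' [label_compound()]. A share of the multi-measurement compounds are exact
#' two-measurement ties with ground truth `"excluded"`.
#'
#' @param n Number of compounds.
#' @param threshold Binder threshold on the logRBA scale.
#' @param multi_measurement_fraction Fraction of compounds with more than
#'   one measurement.
#' @param tie_fraction Fraction of the multi-measurement compounds emitted
#'   as exact ties.
#' @param seed Integer seed.
#' @return List with `records` (long data frame `compound_id`, `logrba`) and
#'   `truth` (data frame `compound_id`, `label` in binder / non_binder /
#'   excluded).
#' @export
generate_logrba_records <- function(n, threshold = -5,
                                    multi_measurement_fraction = 0.25,
                                    tie_fraction = 0.15, seed = 1L) {
  stopifnot(n >= 1, multi_measurement_fraction >= 0,
            multi_measurement_fraction <= 1,
            tie_fraction >= 0, tie_fraction <= 1)
  set.seed(seed)
  ids <- sprintf("A%05d", seq_len(n))
  rec <- vector("list", n)
  truth <- character(n)
  offset <- function(m) abs(stats::rnorm(m, 0, 1.5)) + 1e-6
  for (i in seq_len(n)) {
    multi <- stats::runif(1L) < multi_measurement_fraction
    if (!multi) {
      lab <- sample(c(.BINDER, .NONBINDER), 1L)
      vals <- threshold + if (lab == .BINDER) offset(1L) else -offset(1L)
    } else if (stats::runif(1L) < tie_fraction) {
      lab <- .EXCLUDED
      vals <- threshold + c(offset(1L), -offset(1L))
    } else {
      m <- sample(2:3, 1L)
      lab <- sample(c(.BINDER, .NONBINDER), 1L)
      n_up <- if (lab == .BINDER) m - floor((m - 1L) / 2L) else
        floor((m - 1L) / 2L)  # strict majority of the intended sign
      signs <- sample(rep(c(1, -1), c(n_up, m - n_up)))
      vals <- threshold + signs * offset(m)
    }
    rec[[i]] <- data.frame(compound_id = ids[i], logrba = vals,
                           stringsAsFactors = FALSE)
    truth[i] <- lab
  }
  list(records = do.call(rbind, rec),
       truth = data.frame(compound_id = ids, label = truth,
                          stringsAsFactors = FALSE))
}
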