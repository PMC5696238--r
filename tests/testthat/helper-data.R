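# Shared fixtures, built in code. Expensive study-scale objects are computed
# once per test run and cached.

# tiny dataset with one perfectly separating descriptor plus a noise column
make_separable_dataset <- function(n_per_class = 10L, seed = 42L) {
  set.seed(seed)
  n <- 2L * n_per_class
  x <- cbind(sep = c(stats::rnorm(n_per_class, 5, 0.3),
                     stats::rnorm(n_per_class, -5, 0.3)),
             noise = stats::rnorm(n))
  rownames(x) <- sprintf("S%03d", seq_len(n))
  labeled_dataset(x, rep(c("binder", "non_binder"), each = n_per_class))
}

# small imbalanced dataset with genuine but imperfect signal
make_signal_dataset <- function(n_binders = 48L, n_nonbinders = 12L,
                                n_descriptors = 6L, seed = 3L) {
  gen <- generate_dataset(synth_config(
    n_binders = n_binders, n_nonbinders = n_nonbinders,
    n_descriptors = n_descriptors, n_informative = 2L,
    effect_size = 2, fraction_constant = 0, seed = seed))
  gen$dataset
}

.cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (is.null(.cache[[key]])) .cache[[key]] <- force(expr)
  .cache[[key]]
}

# the scaled study-structure dataset shared by the validation-protocol
# acceptance checks: 500 compounds, 4% non-binders, 50 descriptors of which
# 5 planted informative at the default effect size
scaled_study <- function() {
  cached("scaled_study", {
    gen <- generate_dataset(synth_config(
      n_binders = 480L, n_nonbinders = 20L, n_descriptors = 50L,
      n_informative = 5L, seed = 7L))
    filt <- filter_low_information(gen$dataset$x)
    list(dataset = labeled_dataset(filt$table,
                                   as.character(gen$dataset$y)),
         truth = gen$truth)
  })
}

scaled_study_cv <- function() {
  cached("scaled_study_cv",
         cross_validate(scaled_study()$dataset, k = 5L, iterations = 20L,
                        base_seed = 100L))
}

scaled_study_permutation <- function(replicates = 100L) {
  cached("scaled_study_perm",
         permutation_test(scaled_study()$dataset, replicates = replicates,
                          k = 5L, base_seed = 900L))
}
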