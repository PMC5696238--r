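# JSON persistence for trained forests. The schema stores config, kept
# descriptor names, per-tree descriptor sets and the nested tree nodes, so a
# reloaded model predicts bit-identically.

# doubles are written as %.17g strings: 17 significant digits round-trip
# IEEE doubles exactly, which JSON number emitters do not guarantee
num_out <- function(x) sprintf("%.17g", x)

serialize_node <- function(node) {
  if (node$leaf)
    list(leaf = TRUE, binder_fraction = num_out(node$binder_fraction),
         n_train = node$n_train)
  else
    list(leaf = FALSE, descriptor = node$descriptor,
         threshold = num_out(node$threshold),
         left = serialize_node(node$left),
         right = serialize_node(node$right))
}

deserialize_node <- function(obj) {
  if (!is.list(obj) || is.null(obj$leaf))
    stop("corrupt model file: malformed tree node", call. = FALSE)
  if (isTRUE(obj$leaf)) {
    if (is.null(obj$binder_fraction) || is.null(obj$n_train))
      stop("corrupt model file: leaf missing fields", call. = FALSE)
    list(leaf = TRUE, binder_fraction = as.numeric(obj$binder_fraction),
         n_train = as.integer(obj$n_train))
  } else {
    if (is.null(obj$descriptor) || is.null(obj$threshold) ||
        is.null(obj$left) || is.null(obj$right))
      stop("corrupt model file: internal node missing fields", call. = FALSE)
    list(leaf = FALSE, descriptor = as.character(obj$descriptor),
         threshold = as.numeric(obj$threshold),
         left = deserialize_node(obj$left),
         right = deserialize_node(obj$right))
  }
}

#' Save / load a Decision Forest as JSON
#'
#' `load_model(save_model(m, path))` is the identity: predictions on any
#' probe set are bit-identical before and after the round-trip. Loading a
#' truncated or schema-invalid file is a hard error.
#'
#' @param model A `decision_forest`.
#' @param path JSON file path.
#' @return `save_model` returns `path` invisibly; `load_model` the model.
#' @export
save_model <- function(model, path) {
  stopifnot(inherits(model, "decision_forest"))
  cfg <- unclass(model$config)
  if (is.infinite(cfg$max_depth)) cfg$max_depth <- "Inf"  # JSON has no Inf
  if (is.null(cfg$split_alpha)) cfg$split_alpha <- "none"
  obj <- list(
    format = "erbforest_decision_forest",
    version = 1L,
    config = cfg,
    kept_names = model$kept_names,
    n_train = model$n_train,
    class_counts = as.list(model$class_counts),
    training_balanced_accuracy = model$training_balanced_accuracy,
    descriptor_sets = model$descriptor_sets,
    trees = lapply(model$trees, serialize_node))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  obj <- tryCatch(jsonlite::read_json(path, simplifyVector = FALSE),
                  error = function(e)
                    stop("corrupt model file: ", conditionMessage(e),
                         call. = FALSE))
  if (!identical(obj$format, "erbforest_decision_forest"))
    stop("not an erbforest model file (missing format marker)",
         call. = FALSE)
  need <- c("config", "kept_names", "trees", "descriptor_sets")
  if (!all(need %in% names(obj)))
    stop("corrupt model file: missing ",
         paste(setdiff(need, names(obj)), collapse = ", "), call. = FALSE)
  cfg <- obj$config
  model <- structure(
    list(trees = lapply(obj$trees, deserialize_node),
         descriptor_sets = lapply(obj$descriptor_sets,
                                  function(s) unlist(s, use.names = FALSE)),
         config = forest_config(cfg$max_trees, cfg$min_leaf,
                                if (is.null(cfg$max_depth)) Inf
                                else as.numeric(cfg$max_depth),
                                cfg$improvement_epsilon,
                                if (identical(cfg$split_alpha, "none")) NULL
                                else as.numeric(cfg$split_alpha)),
         kept_names = unlist(obj$kept_names, use.names = FALSE),
         n_train = as.integer(obj$n_train),
         class_counts = c(binder = as.integer(obj$class_counts$binder),
                          non_binder = as.integer(obj$class_counts$non_binder)),
         training_balanced_accuracy =
           unlist(obj$training_balanced_accuracy, use.names = FALSE)),
    class = "decision_forest")
  if (!length(model$trees))
    stop("corrupt model file: no trees", call. = FALSE)
  model
}
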