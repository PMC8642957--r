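# JSON serialization of fitted models (trees, alphas, config, seeds) so a
# trained ensemble can be inspected as plain text and reloaded exactly.

.tree_to_plain <- function(node) {
  if (isTRUE(node$leaf)) {
    list(leaf = TRUE, prop = node$prop, vote = node$vote, n = node$n)
  } else {
    list(leaf = FALSE, feature = node$feature, cut = node$cut,
         left = .tree_to_plain(node$left), right = .tree_to_plain(node$right))
  }
}

.tree_from_plain <- function(node) {
  if (isTRUE(node$leaf)) {
    structure(list(leaf = TRUE, prop = node$prop,
                   vote = as.integer(node$vote), n = as.integer(node$n)),
              class = "lpi_tree")
  } else {
    structure(list(leaf = FALSE, feature = as.integer(node$feature),
                   cut = node$cut,
                   left = .tree_from_plain(node$left),
                   right = .tree_from_plain(node$right)),
              class = "lpi_tree")
  }
}

#' Save / load a fitted ensemble as JSON
#'
#' Full double precision is kept (`digits = NA`), so a reloaded model
#' reproduces predictions exactly.
#'
#' @param model an `lpi_ensemble`.
#' @param path JSON file path.
#' @return `write_model()`: `path`, invisibly.  `read_model()`: the
#'   restored `lpi_ensemble`.
#' @export
write_model <- function(model, path) {
  learners <- lapply(model$learners, function(l) {
    list(family = l$family, alpha = l$alpha, error = l$error,
         model = if (l$family == "extra_tree") {
           list(seed = l$model$seed,
                trees = lapply(l$model$trees, .tree_to_plain))
         } else .tree_to_plain(l$model))
  })
  payload <- list(package = "lpiboost", type = "lpi_ensemble",
                  d = model$d, best_t = model$best_t,
                  best_auc = model$best_auc, history = model$history,
                  tparams = unclass(model$tparams),
                  bparams = unclass(model$bparams),
                  learners = learners)
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
  invisible(path)
}

#' @rdname write_model
#' @export
read_model <- function(path) {
  p <- jsonlite::read_json(path, simplifyVector = FALSE)
  if (!identical(p$type, "lpi_ensemble")) stopf("not an lpi_ensemble file")
  learners <- lapply(p$learners, function(l) {
    model <- if (l$family == "extra_tree") {
      structure(list(trees = lapply(l$model$trees, .tree_from_plain),
                     params = NULL, seed = l$model$seed),
                class = "lpi_forest")
    } else {
      .tree_from_plain(l$model)
    }
    list(model = model, family = l$family, alpha = l$alpha, error = l$error)
  })
  take <- function(x, keys) x[intersect(keys, names(x))]
  tp <- do.call(tree_params, take(p$tparams, c("K", "n_min", "max_depth",
                                               "n_trees", "criterion")))
  bp <- do.call(boost_params, take(p$bparams,
                                   c("max_iter", "patience", "candidates",
                                     "val_fraction", "weight_update",
                                     "init_weights", "retry_cap", "seed")))
  structure(list(learners = learners,
                 history = unlist(p$history),
                 best_t = as.integer(p$best_t), best_auc = p$best_auc,
                 d = as.integer(p$d), tparams = tp, bparams = bp),
            class = "lpi_ensemble")
}
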