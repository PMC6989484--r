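#' Fit a per-feature fitness model
#'
#' The Disease State Index scores each feature with an empirical fitness
#' function built from training-class counts at the observed value. With
#' `P` positives, `N` negatives, `FN(x)` the positives at or below `x` and
#' `FP(x)` the negatives above `x` (in oriented values), the fitness is
#'
#' \deqn{f(x) = FN(x) / (FN(x) + (P/N) FP(x)),}
#'
#' the false-negative rate over the sum of false-negative and false-positive
#' rates at cut-off `x`; the `P/N` factor rescales the negative class so both
#' classes implicitly have equal size. Values below 0.5 indicate the negative
#' class and above 0.5 the positive class. Orientation is chosen from the
#' training data (+1 if the Mann-Whitney AUC of the raw values is >= 0.5,
#' else -1, in which case values are negated internally) so that higher
#' oriented values always indicate the positive class.
#'
#' @param pos_values,neg_values training feature values for the positive and
#'   negative class; `NA`s are dropped.
#' @param feature optional feature name carried in the model.
#' @return object of class `dsi_feature_model` with the sorted oriented
#'   class values, class sizes `P` and `N`, `orientation`, `usable` flag and
#'   `relevance`. A feature with an empty class is marked unusable: its
#'   relevance is 0 and its fitness constant 0.5, so it vanishes from every
#'   relevance-weighted sum.
#' @export
fit_feature <- function(pos_values, neg_values, feature = "") {
  pos <- pos_values[!is.na(pos_values)]
  neg <- neg_values[!is.na(neg_values)]
  if (length(pos) == 0L || length(neg) == 0L) {
    model <- structure(
      list(feature = feature, usable = FALSE, orientation = 1,
           pos = numeric(0), neg = numeric(0),
           P = length(pos), N = length(neg), relevance = 0),
      class = "dsi_feature_model")
    return(model)
  }
  orientation <- if (auc_mw(c(pos, neg),
                            rep(c(TRUE, FALSE), c(length(pos), length(neg)))) >= 0.5) 1 else -1
  model <- structure(
    list(feature = feature, usable = TRUE, orientation = orientation,
         pos = sort(orientation * pos), neg = sort(orientation * neg),
         P = length(pos), N = length(neg), relevance = NA_real_),
    class = "dsi_feature_model")
  model$relevance <- feature_relevance(model)
  model
}

#' Evaluate a feature's fitness function
#'
#' @param model a [fit_feature()] model.
#' @param x numeric vector of feature values; `NA` propagates to `NA`
#'   (missing is never substituted by 0.5 — missing features are skipped and
#'   reweighted at the hierarchy level instead).
#' @return fitness values in \[0, 1\]. In the gap between the classes'
#'   supports both counts can be zero; the 0/0 case returns 0.5 (maximally
#'   uninformative). Unusable models return 0.5 for every non-missing input.
#' @export
fitness <- function(model, x) {
  stopifnot(inherits(model, "dsi_feature_model"))
  out <- rep(NA_real_, length(x))
  obs <- !is.na(x)
  if (!any(obs)) return(out)
  if (!model$usable) {
    out[obs] <- 0.5
    return(out)
  }
  ox <- model$orientation * x[obs]
  fn <- findInterval(ox, model$pos)            # positives <= x
  fp <- model$N - findInterval(ox, model$neg)  # negatives  > x
  denom <- fn + (model$P / model$N) * fp
  f <- ifelse(denom == 0, 0.5, fn / denom)
  out[obs] <- f
  out
}

#' Relevance of a fitted feature
#'
#' Relevance is the Youden index, clamped at zero, of the feature's own
#' fitness classifier evaluated on its training data:
#' `R = max(sensitivity + specificity - 1, 0)`, where a training subject is
#' called positive iff its fitness exceeds 0.5. It measures how well the
#' feature separates the classes and is the feature's weight in the
#' composite index.
#'
#' @param model a [fit_feature()] model.
#' @return relevance in \[0, 1\] (0 for unusable models).
#' @export
feature_relevance <- function(model) {
  stopifnot(inherits(model, "dsi_feature_model"))
  if (!model$usable) return(0)
  # training values are stored oriented; fitness() re-orients its input
  sens <- mean(fitness(model, model$orientation * model$pos) > 0.5)
  spec <- mean(fitness(model, model$orientation * model$neg) <= 0.5)
  max(sens + spec - 1, 0)
}

#' @export
print.dsi_feature_model <- function(x, ...) {
  if (!x$usable) {
    cat(sprintf("DSI feature model `%s`: unusable (a class has no values)\n",
                x$feature))
    return(invisible(x))
  }
  cat(sprintf("DSI feature model `%s`: P=%d, N=%d, orientation %+d, R=%.3f\n",
              x$feature, x$P, x$N, x$orientation, x$relevance))
  invisible(x)
}

# ---- hierarchy ------------------------------------------------------------

#' Build a hierarchy configuration from feature metadata
#'
#' Turns slash-separated category paths (e.g. `"mri/diffusion"`) into the
#' nested node structure the classifier aggregates over. Each node is a list
#' with a `name` and `children`; leaves are lists with a `feature` name.
#'
#' @param feature_meta data.frame with `feature` and `category_path`
#'   columns (see [cohort_table()]), or a cohort.
#' @param features optional subset of features to include.
#' @param root_name name of the root node.
#' @return nested list hierarchy (class `dsi_hierarchy`).
#' @export
build_hierarchy <- function(feature_meta, features = NULL, root_name = "dsi") {
  if (inherits(feature_meta, "cohort_table")) feature_meta <- feature_meta$feature_meta
  if (!is.null(features)) {
    feature_meta <- feature_meta[feature_meta$feature %in% features, , drop = FALSE]
  }
  if (nrow(feature_meta) == 0L) stop("no features to build a hierarchy from", call. = FALSE)

  insert <- function(node, path, feature) {
    if (length(path) == 0L) {
      node$children[[length(node$children) + 1L]] <- list(feature = feature)
      return(node)
    }
    head <- path[1]
    idx <- NULL
    for (i in seq_along(node$children)) {
      ch <- node$children[[i]]
      if (!is.null(ch$name) && ch$name == head) { idx <- i; break }
    }
    if (is.null(idx)) {
      node$children[[length(node$children) + 1L]] <- list(name = head, children = list())
      idx <- length(node$children)
    }
    node$children[[idx]] <- insert(node$children[[idx]], path[-1], feature)
    node
  }

  root <- list(name = root_name, children = list())
  for (i in seq_len(nrow(feature_meta))) {
    path <- strsplit(feature_meta$category_path[i], "/", fixed = TRUE)[[1]]
    # a category holding a single feature of the same top-level name (age,
    # sex, ...) still gets its own node so top-level relevances are uniform
    root <- insert(root, path, feature_meta$feature[i])
  }
  structure(root, class = "dsi_hierarchy")
}

#' Read / write a hierarchy configuration
#'
#' Hierarchies serialize as YAML or JSON nested lists (`name`/`children` for
#' nodes, `feature` for leaves).
#'
#' @param path file path (`.yaml`, `.yml` or `.json`).
#' @return [read_hierarchy()] returns a `dsi_hierarchy`.
#' @export
read_hierarchy <- function(path) {
  h <- if (grepl("\\.json$", path)) {
    jsonlite::read_json(path, simplifyVector = FALSE)
  } else {
    yaml::read_yaml(path)
  }
  structure(h, class = "dsi_hierarchy")
}

#' @rdname read_hierarchy
#' @param hierarchy a `dsi_hierarchy`.
#' @export
write_hierarchy <- function(hierarchy, path) {
  h <- unclass(hierarchy)
  if (grepl("\\.json$", path)) {
    jsonlite::write_json(h, path, auto_unbox = TRUE, pretty = TRUE)
  } else {
    yaml::write_yaml(h, path)
  }
  invisible(path)
}

hierarchy_features <- function(node) {
  if (!is.null(node$feature)) return(node$feature)
  unlist(lapply(node$children, hierarchy_features), use.names = FALSE)
}

#' Fit the Disease State Index hierarchy
#'
#' Fits every leaf's fitness model on the training data, then aggregates
#' bottom-up: each internal node's composite value for a subject is the
#' relevance-weighted mean of its observed children,
#' \deqn{DSI = \sum_i R_i f_i / \sum_i R_i,}
#' with missing children skipped and the weights renormalized over the
#' observed ones — this is what makes the index tolerant of missing data.
#' Node relevance is computed by applying the Youden rule to the node's own
#' composite training values with the classifier "composite > 0.5",
#' recursively up to the root, whose composite is the final DSI.
#'
#' @param features data.frame or matrix of training feature values
#'   (subjects x features, `NA` = missing), or a [cohort_table()].
#' @param labels logical or 0/1 outcome labels (length = subjects); subjects
#'   with a missing label are dropped from the fit.
#' @param hierarchy optional `dsi_hierarchy`; defaults to the hierarchy
#'   implied by the cohort's feature metadata (or a flat hierarchy over the
#'   columns when plain data are given).
#' @return object of class `dsi_model`.
#' @export
dsi_fit <- function(features, labels, hierarchy = NULL) {
  if (inherits(features, "cohort_table")) {
    if (is.null(hierarchy)) hierarchy <- build_hierarchy(features$feature_meta)
    features <- features$features
  }
  features <- as.data.frame(features)
  if (inherits(labels, "outcome_labels")) labels <- labels$labels
  labels <- as_binary_labels(labels)
  if (length(labels) != nrow(features)) {
    stop("labels must have one entry per row of `features`", call. = FALSE)
  }
  keep <- !is.na(labels)
  features <- features[keep, , drop = FALSE]
  labels <- labels[keep]
  if (!any(labels) || all(labels)) {
    stop("training data must contain both classes", call. = FALSE)
  }
  if (is.null(hierarchy)) {
    meta <- data.frame(feature = names(features), category_path = names(features),
                       is_binary = FALSE)
    hierarchy <- build_hierarchy(meta)
  }
  unknown <- setdiff(hierarchy_features(hierarchy), names(features))
  if (length(unknown)) {
    stop("hierarchy references unknown features: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }

  fit_node <- function(node) {
    if (!is.null(node$feature)) {
      x <- features[[node$feature]]
      model <- fit_feature(x[labels], x[!labels], feature = node$feature)
      values <- fitness(model, x)
      return(list(name = node$feature, is_leaf = TRUE, model = model,
                  relevance = model$relevance, train_values = values))
    }
    children <- lapply(node$children, fit_node)
    values <- combine_children(
      vapply(children, function(ch) ch$train_values, numeric(length(labels))),
      vapply(children, function(ch) ch$relevance, numeric(1))
    )
    rel <- node_relevance(values, labels)
    list(name = node$name, is_leaf = FALSE, children = children,
         relevance = rel, train_values = values)
  }

  root <- fit_node(hierarchy)
  structure(list(root = root, hierarchy = hierarchy,
                 n_train = length(labels),
                 P = sum(labels), N = sum(!labels)),
            class = "dsi_model")
}

# Relevance-weighted mean over observed children; rows where no observed
# child has positive relevance are undefined (NA).
combine_children <- function(value_matrix, relevances) {
  vm <- as.matrix(value_matrix)
  obs <- !is.na(vm)
  w <- matrix(relevances, nrow(vm), ncol(vm), byrow = TRUE) * obs
  v0 <- vm
  v0[!obs] <- 0
  den <- rowSums(w)
  num <- rowSums(w * v0)
  out <- ifelse(den > 0, num / den, NA_real_)
  out
}

# Youden relevance of composite training values against the 0.5 cut-off;
# composites already live on the fitness scale. Missing composites are
# excluded; a class with no observed composite gives relevance 0.
node_relevance <- function(values, labels) {
  vp <- values[labels]
  vn <- values[!labels]
  vp <- vp[!is.na(vp)]
  vn <- vn[!is.na(vn)]
  if (length(vp) == 0L || length(vn) == 0L) return(0)
  max(mean(vp > 0.5) + mean(vn <= 0.5) - 1, 0)
}

#' Score subjects with a fitted Disease State Index
#'
#' Evaluates the leaf fitness functions on the subjects' non-missing
#' features and aggregates them through the fitted hierarchy, renormalizing
#' relevance weights over observed children at every node. A subject with no
#' observed descendant anywhere gets a missing DSI. Classification follows
#' the index: positive iff DSI > 0.5, negative iff DSI <= 0.5, undefined if
#' missing.
#'
#' @param model a [dsi_fit()] model.
#' @param newdata data.frame/matrix of feature values or a [cohort_table()].
#' @param subject_id optional ids for the output.
#' @return data.frame (class `dsi_scores`) with `subject_id`, `dsi`,
#'   `classification`.
#' @export
dsi_score <- function(model, newdata, subject_id = NULL) {
  stopifnot(inherits(model, "dsi_model"))
  if (inherits(newdata, "cohort_table")) {
    if (is.null(subject_id)) subject_id <- newdata$subject_id
    newdata <- newdata$features
  }
  newdata <- as.data.frame(newdata)
  n <- nrow(newdata)
  if (is.null(subject_id)) subject_id <- rownames(newdata) %||% as.character(seq_len(n))

  score_node <- function(node) {
    if (isTRUE(node$is_leaf)) {
      x <- newdata[[node$name]]
      if (is.null(x)) x <- rep(NA_real_, n)
      return(fitness(node$model, x))
    }
    vm <- vapply(node$children, score_node, numeric(n))
    if (n == 1L) vm <- matrix(vm, nrow = 1L)
    combine_children(vm, vapply(node$children, function(ch) ch$relevance, numeric(1)))
  }

  dsi <- score_node(model$root)
  classification <- ifelse(is.na(dsi), "undefined",
                           ifelse(dsi > 0.5, "positive", "negative"))
  structure(data.frame(subject_id = subject_id, dsi = dsi,
                       classification = classification,
                       stringsAsFactors = FALSE),
            class = c("dsi_scores", "data.frame"))
}

#' Relevance table of a fitted model
#'
#' @param model a [dsi_fit()] model.
#' @param max_depth prune the listing below this depth (root = 0);
#'   `Inf` lists every node and leaf.
#' @return data.frame with `node`, `depth`, `is_leaf`, `relevance`.
#' @export
dsi_relevances <- function(model, max_depth = Inf) {
  stopifnot(inherits(model, "dsi_model"))
  rows <- list()
  walk <- function(node, depth) {
    if (depth > max_depth) return(invisible())
    rows[[length(rows) + 1L]] <<- data.frame(
      node = node$name, depth = depth, is_leaf = isTRUE(node$is_leaf),
      relevance = node$relevance, stringsAsFactors = FALSE)
    if (!isTRUE(node$is_leaf)) for (ch in node$children) walk(ch, depth + 1L)
  }
  walk(model$root, 0L)
  do.call(rbind, rows)
}

#' @export
print.dsi_model <- function(x, ...) {
  cat(sprintf("Disease State Index model: %d training subjects (%d pos / %d neg)\n",
              x$n_train, x$P, x$N))
  rel <- dsi_relevances(x, max_depth = 1L)
  rel <- rel[rel$depth == 1L, ]
  cat("  top-level relevances:\n")
  for (i in seq_len(nrow(rel))) {
    cat(sprintf("    %-22s R=%.3f\n", rel$node[i], rel$relevance[i]))
  }
  invisible(x)
}
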