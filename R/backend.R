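#' Classifier backend specification
#'
#' The inference contract of the pipeline is expressed as a pluggable,
#' order-preserving batched classifier: any backend honoring it (including a
#' hardware-accelerated one) can be dropped in. Two builtin kinds are
#' provided: a regularized multinomial linear model (`builtin_linear`,
#' default) and a small single-hidden-layer network (`builtin_mlp`).
#'
#' @param kind `"builtin_linear"`, `"builtin_mlp"` or `"external"`.
#' @param batch_size Rows per inference batch (default 512).
#' @param workers Worker count for batch dispatch (default 1); outputs are
#'   emitted in input order for every worker count.
#' @param seed Seed fixing all training/inference stochasticity.
#' @return List of class `vc_backend_spec`.
#' @export
backend_spec <- function(kind = c("builtin_linear", "builtin_mlp", "external"),
                         batch_size = 512, workers = 1, seed = 1) {
  kind <- match.arg(kind)
  if (batch_size < 1) stop_invalid("batch_size must be >= 1")
  structure(
    list(kind = kind, batch_size = as.integer(batch_size),
         workers = as.integer(workers), seed = as.integer(seed)),
    class = "vc_backend_spec"
  )
}

# Registry of feature reducers a head may apply before its model; reducers
# compress wide feature rows to the compact view shallow heads learn from.
head_reducers <- function(name) {
  switch(name,
    pileup_window = reduce_pileup_rows,
    identity = identity,
    abort(sprintf("unknown feature reducer '%s'", name),
          class = "haplocall_backend_error")
  )
}

# Fit one classification head over the classes observed in y. Classes with
# fewer than 3 examples cannot be fit (nor meaningfully validated) and are
# dropped from the head's class set; they are predicted with probability 0.
fit_head <- function(x, y, spec, name = "head", reducer = NULL) {
  p_raw <- ncol(x)
  if (!is.null(reducer)) x <- head_reducers(reducer)(x)
  tab <- table(y)
  rare <- names(tab)[tab < 3]
  if (length(rare)) {
    keep <- !(y %in% rare)
    x <- x[keep, , drop = FALSE]
    y <- y[keep]
  }
  classes <- sort(unique(y))
  scale_sd <- apply(x, 2, stats::sd)
  scale_sd[scale_sd == 0 | is.na(scale_sd)] <- 1
  scale_mu <- colMeans(x)
  xs <- scale(x, center = scale_mu, scale = scale_sd)
  if (length(classes) == 1) {
    return(list(type = "constant", classes = classes, p = p_raw,
                reducer = reducer, name = name))
  }
  set.seed(spec$seed)
  if (spec$kind == "builtin_mlp") {
    yf <- factor(y, levels = classes)
    model <- nnet::nnet(
      x = xs, y = stats::model.matrix(~ yf - 1),
      size = 12, softmax = TRUE, maxit = 300, decay = 1e-3,
      MaxNWts = 1e6, trace = FALSE
    )
    return(list(type = "nnet", model = model, classes = classes, p = p_raw,
                reducer = reducer, mu = scale_mu, sd = scale_sd, name = name))
  }
  fam <- if (length(classes) == 2) "binomial" else "multinomial"
  model <- glmnet::glmnet(
    xs, factor(y, levels = classes), family = fam, alpha = 0,
    lambda = c(1, 0.1, 0.01, 0.001), standardize = FALSE, maxit = 1e6
  )
  list(type = "glmnet", model = model, family = fam, classes = classes,
       p = p_raw, reducer = reducer, mu = scale_mu, sd = scale_sd, name = name)
}

head_predict <- function(head, x) {
  if (!is.matrix(x)) x <- matrix(x, nrow = 1)
  if (ncol(x) != head$p) {
    abort(
      sprintf("feature shape mismatch for %s: expected %d columns, got %d",
              head$name, head$p, ncol(x)),
      class = "haplocall_shape_error"
    )
  }
  n <- nrow(x)
  if (head$type == "constant") {
    out <- matrix(1, nrow = n, ncol = 1, dimnames = list(NULL, head$classes))
    return(out)
  }
  if (!is.null(head$reducer)) x <- head_reducers(head$reducer)(x)
  xs <- scale(x, center = head$mu, scale = head$sd)
  if (head$type == "nnet") {
    pr <- predict(head$model, xs)
    colnames(pr) <- head$classes
  } else if (head$family == "binomial") {
    p2 <- as.numeric(predict(head$model, xs, s = 0.001, type = "response"))
    pr <- cbind(1 - p2, p2)
    colnames(pr) <- head$classes
  } else {
    pr <- predict(head$model, xs, s = 0.001, type = "response")[, , 1]
    if (n == 1) pr <- matrix(pr, nrow = 1, dimnames = list(NULL, names(pr)))
    pr <- pr[, head$classes, drop = FALSE]
  }
  pr / rowSums(pr)
}

#' Batched, order-preserving prediction
#'
#' Splits the feature rows into batches of `spec$batch_size`, dispatches them
#' to `spec$workers` workers, and reassembles the probabilities in input
#' order: output row i always corresponds to input row i, for every batch
#' size and worker count. Per-batch working data is released as soon as the
#' batch completes.
#'
#' @param backend A trained backend (from [train_fixture_models()]) or a
#'   single head.
#' @param features Numeric matrix of feature rows.
#' @param spec Optional [backend_spec()] override (defaults to the backend's
#'   own spec).
#' @return For a single-head backend a probability matrix; for a multi-head
#'   backend a named list of probability matrices (one per task head).
#' @export
batched_predict <- function(backend, features, spec = NULL) {
  spec <- spec %||% backend$spec %||% backend_spec()
  heads <- if (!is.null(backend$heads)) backend$heads else list(main = backend$head %||% backend)
  if (!is.matrix(features)) features <- as.matrix(features)
  n <- nrow(features)
  run_head <- function(head) {
    if (n == 0) {
      return(matrix(numeric(0), nrow = 0, ncol = length(head$classes),
                    dimnames = list(NULL, head$classes)))
    }
    batches <- batch_indices(n, spec$batch_size)
    fun <- function(ix) head_predict(head, features[ix, , drop = FALSE])
    parts <- if (spec$workers > 1) {
      parallel::mclapply(batches, fun, mc.cores = spec$workers)
    } else {
      lapply(batches, fun)
    }
    do.call(rbind, parts)
  }
  out <- lapply(heads, run_head)
  if (length(out) == 1 && identical(names(out), "main")) out[[1]] else out
}

#' Train the fixture classifier backends
#'
#' Trains the pileup genotype head and the three full-alignment task heads
#' (21-genotype, zygosity, indel length) on simulator-labeled features. Sites
#' are split 80/20 into training/validation, stratified by class; held-out
#' accuracy is stored on each backend. Deterministic given `spec$seed`.
#'
#' @param dataset List with `pileup = list(x, y)` and optionally
#'   `full_alignment = list(x, y_gt21, y_zygosity, y_indel_len)`; `x` are
#'   feature matrices, labels character vectors.
#' @param spec A [backend_spec()].
#' @param required_classes Optional named list (per label set) of classes
#'   that must be present in the training labels; a listed class with no
#'   example raises an explicit error naming it.
#' @return List of class `vc_backends` with `pileup` and (if trained)
#'   `full_alignment` backends.
#' @export
train_fixture_models <- function(dataset, spec = backend_spec(),
                                 required_classes = NULL) {
  check_classes <- function(y, req, label) {
    missing <- setdiff(req, unique(y))
    if (length(missing)) {
      abort(
        sprintf("class(es) absent from %s training data: %s",
                label, paste(missing, collapse = ", ")),
        class = "haplocall_missing_class"
      )
    }
  }
  split8020 <- function(y) {
    set.seed(spec$seed)
    val <- logical(length(y))
    for (cl in unique(y)) {
      ix <- which(y == cl)
      n_val <- floor(length(ix) * 0.2)
      if (n_val > 0) val[sample(ix, n_val)] <- TRUE
    }
    val
  }
  train_one <- function(x, y, name, req = NULL, reducer = NULL) {
    if (!is.null(req)) check_classes(y, req, name)
    val <- split8020(y)
    head <- fit_head(x[!val, , drop = FALSE], y[!val], spec, name = name,
                     reducer = reducer)
    acc <- if (any(val)) {
      pr <- head_predict(head, x[val, , drop = FALSE])
      mean(colnames(pr)[max.col(pr, ties.method = "first")] == y[val])
    } else NA_real_
    head$val_accuracy <- acc
    head
  }

  out <- list(spec = spec)
  pu <- dataset$pileup
  pu_head <- train_one(pu$x, pu$y, "pileup_genotype",
                       required_classes$pileup %||% NULL,
                       reducer = pu$reducer %||% "pileup_window")
  out$pileup <- structure(
    list(spec = spec, head = pu_head, kind = spec$kind,
         task = "pileup"),
    class = "vc_backend"
  )
  fa <- dataset$full_alignment
  if (!is.null(fa)) {
    heads <- list(
      gt21 = train_one(fa$x, fa$y_gt21, "gt21", required_classes$gt21 %||% NULL),
      zygosity = train_one(fa$x, fa$y_zygosity, "zygosity",
                           required_classes$zygosity %||% NULL),
      indel_len = train_one(fa$x, fa$y_indel_len, "indel_len",
                            required_classes$indel_len %||% NULL)
    )
    out$full_alignment <- structure(
      list(spec = spec, heads = heads, kind = spec$kind,
           task = "full_alignment"),
      class = "vc_backend"
    )
  }
  structure(out, class = "vc_backends")
}

BACKEND_FORMAT_VERSION <- 1L

#' Save / load a trained backend archive
#'
#' The archive embeds a format version and a digest of the backend
#' configuration and weights; loading refuses an archive whose recomputed
#' digest does not match (corruption or version drift).
#'
#' @param backends A `vc_backends` object.
#' @param path Destination file.
#' @return `path` invisibly (`save_backends`); the backends (`load_backends`).
#' @export
save_backends <- function(backends, path) {
  payload <- unclass(backends)
  saveRDS(
    list(
      format_version = BACKEND_FORMAT_VERSION,
      digest = hash(payload),
      backends = payload
    ),
    path
  )
  invisible(path)
}

#' @rdname save_backends
#' @export
load_backends <- function(path) {
  arc <- readRDS(path)
  if (!identical(arc$format_version, BACKEND_FORMAT_VERSION)) {
    abort(sprintf("unsupported backend archive version %s", arc$format_version),
          class = "haplocall_backend_error")
  }
  if (!identical(hash(arc$backends), arc$digest)) {
    abort("backend archive digest mismatch; refusing to load",
          class = "haplocall_backend_error")
  }
  structure(arc$backends, class = "vc_backends")
}

#' @exportS3Method generics::glance
glance.vc_backend <- function(x, ...) {
  heads <- if (!is.null(x$heads)) x$heads else list(x$head)
  tibble(
    task = x$task,
    kind = x$kind,
    n_heads = length(heads),
    n_classes = sum(vapply(heads, function(h) length(h$classes), integer(1))),
    val_accuracy = mean(vapply(heads, function(h) h$val_accuracy %||% NA_real_,
                               numeric(1)), na.rm = TRUE)
  )
}

#' @exportS3Method generics::tidy
tidy.vc_backend <- function(x, ...) {
  heads <- if (!is.null(x$heads)) x$heads else list(x$head)
  bind_rows(lapply(heads, function(h) {
    tibble(head = h$name, type = h$type, n_classes = length(h$classes),
           classes = paste(h$classes, collapse = ","),
           val_accuracy = h$val_accuracy %||% NA_real_)
  }))
}
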