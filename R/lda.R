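#' Fit a two-class shrinkage LDA model
#'
#' Linear discriminant for move-vs-rest intent detection. Weights solve
#' `S_shrunk w = mean_move - mean_rest` where `S_shrunk` is the pooled
#' within-class covariance shrunk toward the average-eigenvalue identity
#' `(tr(S)/p) I` — the standard small-sample regularization when trials are
#' few. The bias places score 0 at the midpoint of the projected class
#' means; the move class projects positive.
#'
#' @param features numeric matrix, examples x features.
#' @param labels character/factor with exactly two levels.
#' @param positive_class label of the "move" class (projects positive).
#' @param shrinkage shrinkage weight in `[0, 1]` (default 0.1).
#' @return list of class `lda_model`: `weights`, `bias`, `class_means`
#'   (positive/negative rows), `pooled_covariance` (shrunk), `shrinkage`,
#'   `feature_names`, `n_per_class`.
#' @export
fit_lda <- function(features, labels, positive_class, shrinkage = 0.1) {
  features <- as.matrix(features)
  labels <- as.character(labels)
  if (shrinkage < 0 || shrinkage > 1) {
    stop("shrinkage must be in [0, 1]", call. = FALSE)
  }
  classes <- unique(labels)
  if (length(classes) != 2L) {
    stop("labels must contain exactly two classes, got: ",
         paste(classes, collapse = ", "), call. = FALSE)
  }
  if (!positive_class %in% classes) {
    stop("positive_class '", positive_class, "' not among labels",
         call. = FALSE)
  }
  negative_class <- setdiff(classes, positive_class)
  xp <- features[labels == positive_class, , drop = FALSE]
  xn <- features[labels == negative_class, , drop = FALSE]
  if (nrow(xp) < 2L || nrow(xn) < 2L) {
    stop("each class needs >= 2 examples (got ", nrow(xp), " move, ",
         nrow(xn), " rest)", call. = FALSE)
  }
  p <- ncol(features)
  mp <- colMeans(xp)
  mn <- colMeans(xn)
  sp_ <- stats::cov(xp)
  sn_ <- stats::cov(xn)
  s <- ((nrow(xp) - 1) * sp_ + (nrow(xn) - 1) * sn_) /
    (nrow(xp) + nrow(xn) - 2)
  nu <- sum(diag(s)) / p
  s_shrunk <- (1 - shrinkage) * s + shrinkage * nu * diag(p)
  w <- tryCatch(
    solve(s_shrunk, mp - mn),
    error = function(e) {
      stop("pooled covariance is singular; increase shrinkage (got ",
           shrinkage, ")", call. = FALSE)
    }
  )
  bias <- -sum(w * (mp + mn)) / 2
  fn <- colnames(features)
  if (is.null(fn)) fn <- paste0("f", seq_len(p))
  structure(
    list(weights = unname(w), bias = bias,
         class_means = rbind(positive = mp, negative = mn),
         pooled_covariance = s_shrunk, shrinkage = shrinkage,
         feature_names = fn,
         positive_class = positive_class, negative_class = negative_class,
         n_per_class = c(positive = nrow(xp), negative = nrow(xn))),
    class = "lda_model"
  )
}

#' @export
print.lda_model <- function(x, ...) {
  cat(sprintf("<lda_model> %d features, shrinkage %g, %s(+%d) vs %s(%d)\n",
              length(x$weights), x$shrinkage, x$positive_class,
              x$n_per_class[1], x$negative_class, x$n_per_class[2]))
  invisible(x)
}

#' LDA decision score
#'
#' `weights . x + bias`; positive scores indicate the move class.
#'
#' @param model an `lda_model`.
#' @param features numeric vector, or matrix with one example per row.
#' @return numeric score(s).
#' @export
lda_score <- function(model, features) {
  if (is.null(dim(features))) features <- matrix(features, nrow = 1L)
  if (ncol(features) != length(model$weights)) {
    stop("feature dimension ", ncol(features), " != model dimension ",
         length(model$weights), call. = FALSE)
  }
  drop(features %*% model$weights + model$bias)
}

num_fmt <- function(x) sprintf("%.17g", x)

#' Serialize / read an LDA model
#'
#' Versioned plain-text format: one `key: value` line per field, matrices
#' row-major space-separated.
#'
#' @param model an `lda_model`.
#' @param path file path.
#' @export
write_lda_model <- function(model, path) {
  p <- length(model$weights)
  lines <- c(
    "erdswitch_lda_model: 1",
    paste0("features: ", paste(model$feature_names, collapse = " ")),
    paste0("positive_class: ", model$positive_class),
    paste0("negative_class: ", model$negative_class),
    paste0("shrinkage: ", num_fmt(model$shrinkage)),
    paste0("weights: ", paste(num_fmt(model$weights), collapse = " ")),
    paste0("bias: ", num_fmt(model$bias)),
    paste0("mean_positive: ",
           paste(num_fmt(model$class_means["positive", ]), collapse = " ")),
    paste0("mean_negative: ",
           paste(num_fmt(model$class_means["negative", ]), collapse = " ")),
    paste0("covariance: ",
           paste(num_fmt(as.numeric(t(model$pooled_covariance))),
                 collapse = " ")),
    paste0("n_positive: ", model$n_per_class[1]),
    paste0("n_negative: ", model$n_per_class[2])
  )
  if (!is.null(model$band)) {
    lines <- c(lines, paste0("band: ", num_fmt(model$band$low), " ",
                             num_fmt(model$band$high)))
  }
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(lines, con, sep = "\n", useBytes = TRUE)
  invisible(path)
}

#' @rdname write_lda_model
#' @export
read_lda_model <- function(path) {
  lines <- readLines(path)
  kv <- strsplit(lines, ": ", fixed = TRUE)
  keys <- vapply(kv, `[`, "", 1L)
  vals <- vapply(kv, function(x) paste(x[-1], collapse = ": "), "")
  get <- function(k) vals[match(k, keys)]
  nums <- function(k) as.numeric(strsplit(get(k), " ")[[1]])
  if (get("erdswitch_lda_model") != "1") {
    stop("unsupported model file version", call. = FALSE)
  }
  w <- nums("weights")
  p <- length(w)
  model <- structure(
    list(weights = w, bias = nums("bias"),
         class_means = rbind(positive = nums("mean_positive"),
                             negative = nums("mean_negative")),
         pooled_covariance = matrix(nums("covariance"), p, p, byrow = TRUE),
         shrinkage = nums("shrinkage"),
         feature_names = strsplit(get("features"), " ")[[1]],
         positive_class = get("positive_class"),
         negative_class = get("negative_class"),
         n_per_class = c(positive = nums("n_positive"),
                         negative = nums("n_negative"))),
    class = "lda_model"
  )
  if ("band" %in% keys) {
    b <- nums("band")
    model$band <- freq_band(b[1], b[2])
  }
  model
}
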