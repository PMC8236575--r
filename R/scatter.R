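#' Within-, between- and mixture-class scatter matrices
#'
#' Classes are weighted uniformly (1/M each). The within-class matrix is the
#' average of the per-class sample covariances about their own means (1/n_i
#' normalisation, no Bessel correction); the between-class matrix is the
#' average squared deviation of the class means from their grand mean; the
#' mixture matrix is their sum, an identity that holds exactly by
#' construction.
#'
#' @param x Numeric matrix (samples in rows) or a feature tibble from
#'   [extract_features()].
#' @param labels Class labels (ignored when `x` is a feature tibble with a
#'   `label` column).
#' @return An object of class `emg_scatter`: list with `Sw`, `Sb`, `Sm`,
#'   `class_means`, `global_mean`, `classes`.
#' @export
scatter_matrices <- function(x, labels = NULL) {
  if (is.data.frame(x)) {
    fm <- feature_matrix(x)
    if (is.null(labels)) labels <- fm$y
    x <- fm$x
  }
  x <- as.matrix(x)
  if (is.null(labels)) abort("`labels` are required.")
  labels <- factor(labels)
  if (anyNA(labels)) abort("Unknown (NA) label encountered.")
  m <- nlevels(labels)
  if (m < 2L) abort("Need at least two classes.")
  d <- ncol(x)
  sw <- matrix(0, d, d)
  means <- matrix(0, m, d)
  for (i in seq_len(m)) {
    xi <- x[labels == levels(labels)[i], , drop = FALSE]
    if (nrow(xi) == 0L) abort("Every class must be nonempty.")
    ui <- colMeans(xi)
    means[i, ] <- ui
    cx <- sweep(xi, 2L, ui)
    sw <- sw + crossprod(cx) / nrow(xi) / m
  }
  u0 <- colMeans(means)
  cm <- sweep(means, 2L, u0)
  sb <- crossprod(cm) / m
  structure(
    list(
      Sw = sw, Sb = sb, Sm = sw + sb,
      class_means = means, global_mean = u0, classes = levels(labels)
    ),
    class = "emg_scatter"
  )
}

#' Fisher separability criterion J3
#'
#' `J3 = trace(Sw^-1 Sm)`. Since `Sm = Sw + Sb` with `Sb` positive
#' semidefinite, `J3 >= D` always, with equality when the class means
#' coincide. The within-class matrix is ridge-stabilised as
#' `Sw + eps I` with `eps = 1e-8 trace(Sw)/D` before inversion (a 294-dim
#' scatter estimated from a few thousand windows can be ill-conditioned);
#' the same stabilised matrix is used on both sides so the `J3 >= D` bound
#' is preserved.
#'
#' @param x An `emg_scatter` object, or a feature matrix/tibble (then
#'   `labels` must identify the classes).
#' @param labels Class labels when `x` is raw data.
#' @param ridge Relative ridge factor.
#' @return The scalar J3 value.
#' @export
j3_score <- function(x, labels = NULL, ridge = 1e-8) {
  s <- if (inherits(x, "emg_scatter")) x else scatter_matrices(x, labels)
  d <- ncol(s$Sw)
  eps <- ridge * sum(diag(s$Sw)) / d
  sw <- s$Sw + diag(eps, d)
  sol <- tryCatch(solve(sw, s$Sb), error = function(e) NULL)
  if (is.null(sol)) {
    abort(paste(
      "Within-class scatter is singular even after ridge stabilisation;",
      "reduce the feature dimension or add samples."
    ))
  }
  d + sum(diag(sol))
}
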