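new_emg_selection <- function(method, dims, groups = NULL, fitness = NA_real_,
                              trajectory = numeric(), config = list()) {
  structure(
    list(
      method = method, dims = as.integer(dims), groups = groups,
      fitness = fitness, trajectory = trajectory, config = config
    ),
    class = "emg_selection"
  )
}

#' @export
print.emg_selection <- function(x, ...) {
  cat(sprintf("<emg_selection> %s: %d dimensions", x$method, length(x$dims)))
  if (!is.null(x$groups)) {
    cat(sprintf(" from groups [%s]", paste(x$groups, collapse = ", ")))
  }
  if (!is.na(x$fitness)) cat(sprintf(", validation accuracy %.3f", x$fitness))
  cat("\n")
  invisible(x)
}

#' Baseline: keep every feature dimension
#'
#' @param features Feature tibble (or matrix) defining the dimensionality.
#' @return An `emg_selection` with the identity mask.
#' @export
nfs_select <- function(features) {
  d <- if (is.data.frame(features)) sum(grepl("^dim_", names(features)))
       else ncol(features)
  new_emg_selection("NFS", seq_len(d))
}

# J3 on a subset of dimensions of precomputed full scatter matrices.
j3_subset <- function(scatter, dims, ridge = 1e-8) {
  sw <- scatter$Sw[dims, dims, drop = FALSE]
  sb <- scatter$Sb[dims, dims, drop = FALSE]
  d <- length(dims)
  eps <- ridge * sum(diag(sw)) / d
  d + sum(diag(solve(sw + diag(eps, d), sb)))
}

#' Sequential forward selection over the 14 feature groups
#'
#' Greedy growth of a set of feature groups (whole per-feature column blocks
#' across all channels) by the J3 separability criterion: seed with the
#' single best group, then repeatedly add the group whose union with the
#' current set yields the highest J3, stopping when no remaining group
#' strictly increases it (tolerance `1e-9`). Ties break deterministically in
#' layout order. Scatter matrices are computed once on the full data and
#' subsetted, which is exact because scatter restricts to coordinate
#' subsets.
#'
#' @param features Feature tibble from [extract_features()], or a matrix
#'   with `labels` supplied.
#' @param labels Class labels when `features` is a matrix.
#' @param layout The [feature_layout()] describing the column blocks.
#' @param tol Minimum J3 increase to keep adding groups.
#' @return An `emg_selection`; `dims` concatenates the selected groups in
#'   selection order, `trajectory` holds the (strictly increasing) J3 path.
#' @export
sfs_select <- function(features, labels = NULL, layout = feature_layout(),
                       tol = 1e-9) {
  scat <- scatter_matrices(features, labels)
  groups <- feature_groups(layout)
  d_full <- layout_total(layout)
  if (ncol(scat$Sw) != d_full) {
    abort(sprintf("Layout expects %d dimensions but data has %d.",
                  d_full, ncol(scat$Sw)))
  }
  remaining <- names(groups)
  selected <- character()
  dims <- integer()
  trajectory <- numeric()
  current <- -Inf
  while (length(remaining) > 0L) {
    scores <- vapply(remaining, function(g) {
      j3_subset(scat, c(dims, groups[[g]]))
    }, numeric(1))
    best <- which.max(scores)
    if (scores[best] <= current + tol) break
    g <- remaining[best]
    selected <- c(selected, g)
    dims <- c(dims, groups[[g]])
    trajectory <- c(trajectory, scores[best])
    current <- scores[best]
    remaining <- setdiff(remaining, g)
  }
  new_emg_selection("SFS", dims, groups = selected, trajectory = trajectory)
}

#' Stratified one-fifth validation split
#'
#' @param y Factor of class labels.
#' @param seed Integer seed controlling the split.
#' @return Integer vector of validation-row indices (one fifth per class).
#' @keywords internal
stratified_fifth <- function(y, seed) {
  y <- factor(y)
  old <- get0(".Random.seed", envir = globalenv(), ifnotfound = NULL)
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  }, add = TRUE)
  set.seed(seed)
  idx <- unlist(lapply(levels(y), function(l) {
    rows <- which(y == l)
    sample(rows, max(1L, round(length(rows) / 5)))
  }))
  sort(idx)
}

#' Validation accuracy of a dimension subset
#'
#' Splits the day-1 feature vectors into a stratified four-fifths training
#' and one-fifth validation set, z-scores each kept dimension on the
#' training part, fits a linear SVM and returns the validation accuracy.
#' This is the fitness used by PSO feature selection.
#'
#' @param features Feature tibble or matrix of day-1 vectors.
#' @param dims Integer indices of the kept dimensions (nonempty).
#' @param labels Class labels when `features` is a matrix.
#' @param seed Seed for the split.
#' @param cost SVM cost parameter.
#' @return Accuracy fraction in `[0, 1]`.
#' @export
validate_selection <- function(features, dims, labels = NULL, seed = 1L,
                               cost = 1) {
  if (is.data.frame(features)) {
    fm <- feature_matrix(features)
    x <- fm$x
    y <- fm$y
  } else {
    x <- as.matrix(features)
    y <- factor(labels)
  }
  if (length(dims) == 0L) abort("`dims` must be nonempty.")
  val <- stratified_fifth(y, seed)
  if (nlevels(droplevels(y[-val])) < 2L) {
    abort("Degenerate split: training part has fewer than two classes.")
  }
  fit_mask_accuracy(x, y, dims, train = setdiff(seq_along(y), val),
                    test = val, cost = cost)
}

# Train a linear SVM on x[train, dims] (z-scored on the training rows) and
# return accuracy on x[test, dims].
fit_mask_accuracy <- function(x, y, dims, train, test, cost = 1) {
  xt <- x[train, dims, drop = FALSE]
  mu <- colMeans(xt)
  sc <- apply(xt, 2L, stats::sd)
  sc[sc == 0 | !is.finite(sc)] <- 1
  xt <- sweep(sweep(xt, 2L, mu), 2L, sc, "/")
  xv <- sweep(sweep(x[test, dims, drop = FALSE], 2L, mu), 2L, sc, "/")
  fit <- e1071::svm(xt, droplevels(y[train]), kernel = "linear", cost = cost,
                    scale = FALSE)
  mean(as.character(predict(fit, xv)) == as.character(y[test]))
}

#' Particle swarm configuration
#'
#' Defaults follow common PSO feature-selection practice: 80 particles, 50
#' iterations, constriction factor 0.7, cognitive and social learning
#' factors both 2, fresh uniform random factors per dimension per step.
#' Particles move in the continuous unit cube; a dimension is included when
#' its coordinate exceeds `inclusion_threshold`. Velocities are clamped to
#' `velocity_clamp` per step.
#'
#' @param n_particles Swarm size.
#' @param max_iterations Update iterations after the initial evaluation.
#' @param w Inertia (constriction) factor.
#' @param c1,c2 Cognitive and social learning factors.
#' @param velocity_clamp Per-step velocity bound.
#' @param inclusion_threshold Position above which a dimension is included.
#' @param seed Mandatory seed; governs the swarm and the validation split.
#' @return An object of class `emg_pso_config`.
#' @export
pso_config <- function(n_particles = 80L, max_iterations = 50L, w = 0.7,
                       c1 = 2, c2 = 2, velocity_clamp = 0.5,
                       inclusion_threshold = 0.5, seed = 1L) {
  stopifnot(n_particles >= 1L, max_iterations >= 0L, w > 0, w < 1,
            inclusion_threshold > 0, inclusion_threshold < 1)
  structure(
    list(
      n_particles = as.integer(n_particles),
      max_iterations = as.integer(max_iterations),
      w = w, c1 = c1, c2 = c2,
      velocity_clamp = velocity_clamp,
      inclusion_threshold = inclusion_threshold,
      seed = as.integer(seed)
    ),
    class = "emg_pso_config"
  )
}

#' PSO feature-dimension selection
#'
#' Real-coded particle swarm over the unit cube: each particle's position
#' decodes to the dimension mask of coordinates above the inclusion
#' threshold, and its fitness is the validation accuracy of a linear SVM on
#' the day-1 four-fifths/one-fifth split ([validate_selection()]'s
#' protocol). The split is fixed once per run so fitness values are
#' comparable across particles and iterations. An empty mask scores 0 and
#' is never selected.
#'
#' @param features Feature tibble or matrix of day-1 vectors.
#' @param labels Class labels when `features` is a matrix.
#' @param config An [pso_config()].
#' @param cost SVM cost parameter.
#' @return An `emg_selection`; `trajectory` holds the global-best fitness
#'   after the initial evaluation and each iteration (non-decreasing).
#' @export
pso_select <- function(features, labels = NULL, config = pso_config(),
                       cost = 1) {
  if (is.data.frame(features)) {
    fm <- feature_matrix(features)
    x <- fm$x
    y <- fm$y
  } else {
    x <- as.matrix(features)
    y <- factor(labels)
  }
  d <- ncol(x)
  val <- stratified_fifth(y, config$seed)
  train <- setdiff(seq_along(y), val)
  fitness <- function(pos) {
    dims <- which(pos > config$inclusion_threshold)
    if (length(dims) == 0L) return(0)
    fit_mask_accuracy(x, y, dims, train, test = val, cost = cost)
  }
  old <- get0(".Random.seed", envir = globalenv(), ifnotfound = NULL)
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  }, add = TRUE)
  set.seed(config$seed)
  np <- config$n_particles
  pos <- matrix(runif(d * np), nrow = d)
  vel <- matrix(0, d, np)
  fit <- apply(pos, 2L, fitness)
  pbest <- pos
  pbest_fit <- fit
  g <- which.max(fit)
  gbest <- pos[, g]
  gbest_fit <- fit[g]
  trajectory <- gbest_fit
  if (config$max_iterations > 0L) {
    for (t in seq_len(config$max_iterations)) {
      for (j in seq_len(np)) {
        r1 <- runif(d)
        r2 <- runif(d)
        v <- config$w * vel[, j] +
          config$c1 * r1 * (pbest[, j] - pos[, j]) +
          config$c2 * r2 * (gbest - pos[, j])
        v <- pmin(pmax(v, -config$velocity_clamp), config$velocity_clamp)
        p <- pmin(pmax(pos[, j] + v, 0), 1)
        vel[, j] <- v
        pos[, j] <- p
        f <- fitness(p)
        if (f > pbest_fit[j]) {
          pbest[, j] <- p
          pbest_fit[j] <- f
        }
        if (f > gbest_fit) {
          gbest <- p
          gbest_fit <- f
        }
      }
      trajectory <- c(trajectory, gbest_fit)
    }
  }
  new_emg_selection(
    "PSO",
    dims = which(gbest > config$inclusion_threshold),
    fitness = gbest_fit, trajectory = trajectory, config = config
  )
}
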