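#' Solve the steady-state diffusion field for a source configuration
#'
#' Computes the stationary solution of \eqn{D \nabla^2 u - \gamma u = 0} on
#' the unit-spacing lattice with the standard 5-point Laplacian, absorbing
#' (zero-Dirichlet ghost) boundaries, and every source pixel held at its disk
#' value as a Dirichlet constraint. The discrete equation at each non-source
#' pixel `i` is
#' \deqn{(4D + \gamma)\, u_i - D \sum_{n \in N(i)} u_n = 0,}
#' where neighbors outside the lattice contribute zero. The system is
#' assembled as a sparse matrix and solved directly; for `gamma > 0` the
#' operator is strictly diagonally dominant, so the system is non-singular and
#' the solution obeys the discrete maximum principle
#' (`0 <= u <= max` disk value).
#'
#' @param config a [source_configuration()].
#' @param input optional pre-rasterized input image ([rasterize()] output);
#'   recomputed from `config` when missing.
#' @param tol residual-norm bound asserted after the solve.
#' @return An `L` x `L` numeric matrix: the stationary field.
#' @export
solve_steady_state <- function(config, input = NULL, tol = 1e-10) {
  stopifnot(inherits(config, "source_configuration"))
  if (is.null(input)) input <- rasterize(config)
  solve_field(input, config$grid, tol = tol)
}

#' Solve the stationary field for an arbitrary Dirichlet source layout
#'
#' Lower-level interface behind [solve_steady_state()]: any pixel of `input`
#' with a positive value is held fixed at that value (Dirichlet constraint)
#' and the stationary diffusion-decay field is solved on the remaining
#' pixels. Useful for non-disk layouts such as strip sources.
#'
#' @param input `L` x `L` matrix; positive entries are source constraints.
#' @param grid a [grid_spec()] with matching `L`.
#' @param tol residual-norm bound asserted after the solve.
#' @return An `L` x `L` numeric matrix.
#' @export
solve_field <- function(input, grid, tol = 1e-10) {
  stopifnot(inherits(grid, "grid_spec"))
  L <- grid$L
  D <- grid$D
  gam <- grid$gamma
  stopifnot(is.matrix(input), all(dim(input) == c(L, L)))

  n <- L * L
  src <- which(input > 0)
  free <- if (length(src)) seq_len(n)[-src] else seq_len(n)

  # triplets: Dirichlet rows for source pixels, 5-point stencil for the rest
  ii <- c(src, free)
  jj <- c(src, free)
  xx <- c(rep(1, length(src)), rep(4 * D + gam, length(free)))

  if (length(free)) {
    fi <- ((free - 1L) %% L) + 1L      # matrix row (1-based)
    fj <- ((free - 1L) %/% L) + 1L     # matrix col (1-based)
    for (d in list(c(-1L, 0L), c(1L, 0L), c(0L, -1L), c(0L, 1L))) {
      ni <- fi + d[1L]
      nj <- fj + d[2L]
      keep <- ni >= 1L & ni <= L & nj >= 1L & nj <= L
      ii <- c(ii, free[keep])
      jj <- c(jj, ni[keep] + (nj[keep] - 1L) * L)
      xx <- c(xx, rep(-D, sum(keep)))
    }
  }

  A <- Matrix::sparseMatrix(i = ii, j = jj, x = xx, dims = c(n, n))
  b <- numeric(n)
  b[src] <- input[src]
  u <- tryCatch(as.numeric(Matrix::solve(A, b)),
                error = function(e) stop("sparse stationary solve failed: ",
                                         conditionMessage(e)))
  res <- sqrt(sum((as.numeric(A %*% u) - b)^2))
  if (!is.finite(res) || res > tol)
    stop(sprintf("stationary solve residual norm %.3e exceeds tolerance %.1e", res, tol))
  matrix(u, L, L)
}

#' Generate a paired source-layout / steady-field dataset
#'
#' Draws `n_samples` independent source configurations, rasterizes each into
#' the input image, solves the stationary diffusion problem for the target
#' field, and splits the pairs into train and test sets by `split_fraction`
#' (first fraction of samples train, remainder test; samples are i.i.d.).
#' The whole dataset is a pure function of `seed`.
#'
#' @param n_samples number of pairs (>= 2).
#' @param seed integer seed controlling sampling.
#' @param grid a [grid_spec()].
#' @param radius disk radius in pixels.
#' @param n_disks disks per configuration.
#' @param split_fraction train fraction (default 0.8).
#' @return An object of class `diff_dataset`: list with `inputs` and `targets`
#'   (`L x L x n_samples` arrays), `train_idx`, `test_idx`, and `meta`.
#' @export
generate_dataset <- function(n_samples, seed, grid = grid_spec(), radius = 5,
                             n_disks = 2L, split_fraction = 0.8) {
  stopifnot(n_samples >= 2, split_fraction > 0, split_fraction < 1)
  L <- grid$L
  inputs <- array(0, dim = c(L, L, n_samples))
  targets <- array(0, dim = c(L, L, n_samples))
  with_seed(derive_seed(seed, "sampling"), {
    for (k in seq_len(n_samples)) {
      pair <- tryCatch({
        cfg <- sample_configuration(grid, radius = radius, n_disks = n_disks)
        x <- rasterize(cfg)
        list(x = x, y = solve_steady_state(cfg, input = x))
      }, error = function(e) stop(sprintf("sample %d failed: %s", k,
                                          conditionMessage(e))))
      inputs[, , k] <- pair$x
      targets[, , k] <- pair$y
    }
  })
  n_train <- round(split_fraction * n_samples)
  structure(list(
    inputs = inputs,
    targets = targets,
    train_idx = seq_len(n_train),
    test_idx = seq(n_train + 1L, n_samples),
    meta = list(L = L, D = grid$D, gamma = grid$gamma, radius = radius,
                n_disks = n_disks, n_samples = n_samples, seed = seed,
                split_fraction = split_fraction, format_version = 1L)
  ), class = "diff_dataset")
}

#' @export
print.diff_dataset <- function(x, ...) {
  m <- x$meta
  cat(sprintf("<diff_dataset> %d pairs on %d x %d grid (train %d / test %d), radius %g, seed %s\n",
              m$n_samples, m$L, m$L, length(x$train_idx), length(x$test_idx),
              m$radius, format(m$seed)))
  invisible(x)
}

#' Save / load a dataset container
#'
#' The container keeps the paired arrays (`inputs`, `targets`), the index
#' vectors (`train_idx`, `test_idx`) and the generation metadata (grid,
#' radius, sample count, seed, split fraction, format version) in a single
#' serialized file.
#'
#' @param dataset a `diff_dataset`.
#' @param path file path.
#' @return `dataset_save` returns `path` invisibly; `dataset_load` returns the
#'   `diff_dataset`.
#' @export
dataset_save <- function(dataset, path) {
  stopifnot(inherits(dataset, "diff_dataset"))
  saveRDS(dataset, path)
  invisible(path)
}

#' @rdname dataset_save
#' @export
dataset_load <- function(path) {
  ds <- readRDS(path)
  if (!inherits(ds, "diff_dataset"))
    stop("file does not contain a diff_dataset")
  if (!identical(ds$meta$format_version, 1L))
    stop("unsupported dataset format_version: ", ds$meta$format_version)
  ds
}

# Slice a dataset split into network tensors (H, W, 1, n).
dataset_tensors <- function(dataset, split = c("train", "test")) {
  split <- match.arg(split)
  idx <- if (split == "train") dataset$train_idx else dataset$test_idx
  L <- dataset$meta$L
  x <- dataset$inputs[, , idx, drop = FALSE]
  y <- dataset$targets[, , idx, drop = FALSE]
  dim(x) <- c(L, L, 1L, length(idx))
  dim(y) <- c(L, L, 1L, length(idx))
  list(x = x, y = y)
}
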