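# Synthetic embryo profile datasets with known ground-truth gel parameters.

# Evaluate code with a local, explicit RNG seed without disturbing the
# caller's random state.
#' @noRd
with_seed <- function(seed, code) {
  stopifnot(is.numeric(seed), length(seed) == 1L)
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

#' Construct a co-registered embryo profile dataset
#'
#' Bundles the anterior–posterior profiles measured (or synthesised) for one
#' embryo or condition: flow velocity `v` (micrometres/min), velocity
#' gradient `dvdx` (1/min; the compression rate is `-dvdx`), nematic order
#' `Q`, optional myosin concentration `c_prof` (arbitrary units) and
#' optional outer ingression distance `u` (micrometres), all on a shared
#' grid `x` (micrometres, embryo centre at 0).
#'
#' @param x strictly increasing AP grid, micrometres.
#' @param v,dvdx,Q numeric profiles on `x`.
#' @param c_prof optional non-negative myosin profile on `x`.
#' @param u optional non-negative ingression profile on `x`.
#' @param noise_sigma_Q standard deviation of the Gaussian measurement noise
#'   on `Q`, if known (metadata only).
#' @param truth optional [gel_parameters()] that generated `Q`.
#' @return an object of class `embryo_dataset`.
#' @export
embryo_dataset <- function(x, v, dvdx, Q, c_prof = NULL, u = NULL,
                           noise_sigma_Q = NA_real_, truth = NULL) {
  assert_grid(x)
  n <- length(x)
  stopifnot(length(v) == n, length(dvdx) == n, length(Q) == n)
  if (!is.null(c_prof)) stopifnot(length(c_prof) == n, all(c_prof >= 0))
  if (!is.null(u)) stopifnot(length(u) == n, all(u >= -1e-12))
  structure(list(x = x, v = v, dvdx = dvdx, Q = as.numeric(Q),
                 c_prof = c_prof, u = u, noise_sigma_Q = noise_sigma_Q,
                 truth = truth),
            class = "embryo_dataset")
}

#' Generate synthetic embryo datasets from the gel model
#'
#' Produces `n_embryos` co-registered profile sets whose nematic order is
#' the steady-state solution of the gel model for the given flow (plus
#' i.i.d. Gaussian measurement noise), standing in for averaged cortical
#' imaging data.
#'
#' @param gel a [gel_parameters()] object (the ground truth; stored in each
#'   dataset).
#' @param flow a [flow_profile_spec()].
#' @param myosin optional myosin band specification: a list with elements
#'   `baseline`, `amplitude`, `center` (micrometres) and `width`
#'   (micrometres, Gaussian sigma); the profile is
#'   `baseline + amplitude * exp(-(x-center)^2/(2 width^2))`. Required for
#'   a nonzero active-alignment term.
#' @param noise_sigma_Q standard deviation of additive Gaussian noise on Q.
#' @param n_embryos number of replicate datasets.
#' @param seed integer seed; identical seeds give identical datasets.
#' @return list of [embryo_dataset()] objects.
#' @export
generate_embryo_dataset <- function(gel, flow, myosin = NULL,
                                    noise_sigma_Q = 0, n_embryos = 1,
                                    seed = 1) {
  stopifnot(inherits(gel, "gel_parameters"))
  vp <- generate_flow_profile(flow)
  c_prof <- NULL
  if (!is.null(myosin)) {
    stopifnot(all(c("baseline", "amplitude", "center", "width") %in% names(myosin)))
    c_prof <- myosin$baseline +
      myosin$amplitude * exp(-(vp$x - myosin$center)^2 / (2 * myosin$width^2))
  }
  Q0 <- as.numeric(solve_steady_Q(vp$x, vp$v, vp$dvdx, gel, c_prof = c_prof))
  with_seed(seed, {
    lapply(seq_len(n_embryos), function(i) {
      Q <- Q0 + stats::rnorm(length(Q0), sd = noise_sigma_Q)
      embryo_dataset(vp$x, vp$v, vp$dvdx, Q, c_prof = c_prof,
                     noise_sigma_Q = noise_sigma_Q, truth = gel)
    })
  })
}

#' Average a list of embryo datasets profile-wise
#'
#' @param datasets list of [embryo_dataset()] objects on a common grid.
#' @return a single [embryo_dataset()] with per-point mean profiles.
#' @export
average_embryo_datasets <- function(datasets) {
  stopifnot(length(datasets) >= 1L,
            all(vapply(datasets, inherits, TRUE, "embryo_dataset")))
  x <- datasets[[1L]]$x
  for (d in datasets)
    if (!isTRUE(all.equal(d$x, x))) stop("datasets must share a common grid")
  avg <- function(field) {
    cols <- lapply(datasets, `[[`, field)
    if (any(vapply(cols, is.null, TRUE))) return(NULL)
    rowMeans(do.call(cbind, cols))
  }
  embryo_dataset(x, avg("v"), avg("dvdx"), avg("Q"),
                 c_prof = avg("c_prof"), u = avg("u"),
                 noise_sigma_Q = datasets[[1L]]$noise_sigma_Q,
                 truth = datasets[[1L]]$truth)
}

#' Write / read an embryo dataset as CSV with a JSON ground-truth sidecar
#'
#' Profiles go to a plain CSV with columns `x_um`, `v_um_per_min`,
#' `dvdx_per_min`, `Q`, `c`, `u_um` (missing profiles written as `NA`);
#' the generating parameters, when present, to `<path>.truth.json`.
#'
#' @param dataset an [embryo_dataset()].
#' @param path CSV file path.
#' @return `path`, invisibly (`write`); an [embryo_dataset()] (`read`).
#' @export
write_embryo_dataset <- function(dataset, path) {
  stopifnot(inherits(dataset, "embryo_dataset"))
  n <- length(dataset$x)
  df <- data.frame(x_um = dataset$x, v_um_per_min = dataset$v,
                   dvdx_per_min = dataset$dvdx, Q = dataset$Q,
                   c = if (is.null(dataset$c_prof)) rep(NA_real_, n) else dataset$c_prof,
                   u_um = if (is.null(dataset$u)) rep(NA_real_, n) else dataset$u)
  utils::write.csv(df, path, row.names = FALSE)
  if (!is.null(dataset$truth)) {
    jsonlite::write_json(unclass(dataset$truth),
                         paste0(path, ".truth.json"), auto_unbox = TRUE,
                         digits = NA)
  }
  invisible(path)
}

#' @rdname write_embryo_dataset
#' @export
read_embryo_dataset <- function(path) {
  df <- utils::read.csv(path)
  truth_path <- paste0(path, ".truth.json")
  truth <- NULL
  if (file.exists(truth_path)) {
    tj <- jsonlite::read_json(truth_path, simplifyVector = TRUE)
    truth <- gel_parameters(tj$tau, tj$beta_tau, tj$ell, tj$lambda_tau,
                            tj$C1, tj$C2)
  }
  embryo_dataset(df$x_um, df$v_um_per_min, df$dvdx_per_min, df$Q,
                 c_prof = if (all(is.na(df$c))) NULL else df$c,
                 u = if (all(is.na(df$u_um))) NULL else df$u_um,
                 truth = truth)
}
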