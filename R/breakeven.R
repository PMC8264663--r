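#' Break-even count for a surrogate workflow
#'
#' Building a surrogate costs `M * delta` seconds of direct solves for the
#' training set plus `E` seconds of training; each surrogate evaluation then
#' costs `epsilon` instead of `delta` seconds. Equating total direct time
#' `N * delta` with total surrogate-workflow time `M * delta + E + N * epsilon`
#' gives the number of evaluations at which the two workflows cost the same:
#' \deqn{N_{min} = \frac{M + E/\delta}{1 - \epsilon/\delta} \approx M + E/\delta.}
#' Beyond `N_min` replicas the surrogate workflow is strictly faster.
#'
#' @param M training-set size (number of direct solves to generate it).
#' @param E training time, seconds.
#' @param delta direct-solve time per replica, seconds.
#' @param epsilon surrogate inference time per replica, seconds; must be
#'   smaller than `delta` for a break-even to exist.
#' @return The break-even replica count (a real number).
#' @export
n_min <- function(M, E, delta, epsilon) {
  stopifnot(M >= 0, E >= 0, delta > 0, epsilon >= 0)
  if (epsilon >= delta)
    stop("no break-even exists: surrogate inference is not faster (epsilon >= delta)")
  (M + E / delta) / (1 - epsilon / delta)
}

#' Total workflow times for N replicas
#'
#' Returns the direct time `N * delta` and the surrogate-workflow time
#' `M * delta + E + N * epsilon`; the two are equal at `N =` [n_min()].
#'
#' @inheritParams n_min
#' @param N number of replica evaluations (>= 0).
#' @return List with `t_direct` and `t_neuro`, seconds.
#' @export
workflow_times <- function(M, E, delta, epsilon, N) {
  stopifnot(N >= 0)
  list(t_direct = N * delta, t_neuro = M * delta + E + N * epsilon)
}

# "12h"/"30m"/"45s" -> seconds (plain numbers pass through); CLI convenience.
parse_duration <- function(x) {
  if (is.numeric(x)) return(as.double(x))
  m <- regmatches(x, regexec("^([0-9.]+)\\s*([hms]?)$", trimws(x)))[[1]]
  if (length(m) == 0L) stop("cannot parse duration: ", x)
  val <- as.double(m[2])
  val * switch(ifelse(m[3] == "", "s", m[3]), h = 3600, m = 60, s = 1)
}
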