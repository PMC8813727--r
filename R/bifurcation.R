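#' One-parameter Hopf point of the mass model
#'
#' Bisects a free parameter for the value at which the leading eigenvalue
#' pair of the mass-model Jacobian (at the principal fixed point) crosses
#' the imaginary axis with nonzero frequency.
#'
#' @param p A [mass_params()] object.
#' @param free Parameter name (default `"kappa_v"`).
#' @param bracket Interval with a sign change of the leading real part.
#' @param tol Bisection tolerance.
#' @return A list with `value` (critical parameter) and `omega`
#'   (frequency at crossing, rad/ms).
#' @examples
#' \donttest{
#' hopf_point_1param(mass_params(eta0 = 1, kappa_s = 1), bracket = c(0.5, 1.5))
#' }
#' @export
hopf_point_1param <- function(p, free = "kappa_v", bracket, tol = 1e-8) {
  lead <- function(val) {
    pp <- set_param(p, free, val)
    fps <- mass_fixed_points(pp)
    if (length(fps) == 0) stop("fixed point disappeared inside the bracket ",
                               "(fold bifurcation); shrink the bracket")
    R0s <- vapply(fps, function(f) f$state[["R"]], numeric(1))
    fps[[which.max(R0s)]]$eigenvalues[1]
  }
  g <- function(val) Re(lead(val))
  if (g(bracket[1]) * g(bracket[2]) > 0)
    stop("no eigenvalue sign change across the bracket")
  root <- stats::uniroot(g, bracket, tol = tol)$root
  list(value = root, omega = abs(Im(lead(root))))
}

# classify a post-transient trajectory segment of one variable
classify_attractor <- function(x, dt, amp_tol = 1e-4) {
  ex <- oscillation_extrema(x, transient_fraction = 0, dt = dt)
  amp <- ex$max - ex$min
  type <- if (amp > amp_tol && ex$n_peaks >= 5) "limit-cycle"
  else if (amp <= amp_tol) "fixed-point"
  else "undetermined"
  list(type = type, min = ex$min, max = ex$max, period = ex$period)
}

#' Attractor sweep over one parameter of the E-I model
#'
#' For each value of the swept parameter, integrates the E-I model from
#' several initial conditions -- continuation from the previous attractor
#' (forward and backward sweeps), a small perturbation of the current
#' fixed point, and a large-amplitude kick -- classifies the
#' post-transient behaviour of `R_E` and `R_I`, and groups the stable
#' attractors found.  Distinct coexisting oscillations are reported as
#' bistability windows.  Unstable branches are not continued; coexistence
#' is established from stable attractors only.
#'
#' @param p An [ei_params()] object.
#' @param free Parameter name (e.g. `"eta0_I"`).
#' @param values Sweep grid (increasing).
#' @param T,dt Integration horizon and output step per point, ms.
#' @param transient Fraction discarded before classification.
#' @param amp_tol Peak-to-peak amplitude below which a trajectory counts
#'   as a fixed point.
#' @param distinct_tol Minimum difference in the `R_I` oscillation
#'   signature (max and amplitude) for two attractors to count as
#'   distinct branches.
#' @return A list with `table` (data.frame: `value, ic, type, min_R_E,
#'   max_R_E, min_R_I, max_R_I, period`) and `coexistence` (data.frame of
#'   windows with >= 2 distinct stable oscillatory attractors: `lower,
#'   upper`).
#' @export
sweep_attractors <- function(p, free = "eta0_I",
                             values = seq(-12, 6, by = 0.25),
                             T = 400, dt = 0.02, transient = 0.5,
                             amp_tol = 1e-3, distinct_tol = 0.05) {
  run_one <- function(pp, s0, horizon = T) {
    tryCatch({
      run <- simulate_ei(pp, s0 = s0, T = horizon, dt = dt,
                         transient = transient)
      tr <- run$trajectory
      keep <- tr$t >= transient * horizon
      cE <- classify_attractor(tr$R_E[keep], dt, amp_tol)
      cI <- classify_attractor(tr$R_I[keep], dt, amp_tol)
      type <- if (cE$type == "limit-cycle" || cI$type == "limit-cycle")
        "limit-cycle" else cE$type
      list(type = type,
           min_R_E = cE$min, max_R_E = cE$max,
           min_R_I = cI$min, max_R_I = cI$max,
           period = cI$period,
           end = unlist(tr[nrow(tr), ei_state_names]))
    }, error = function(e) NULL)
  }
  rows <- list()
  ends <- list()
  add_row <- function(v, ic, res) {
    rows[[length(rows) + 1]] <<- data.frame(
      value = v, ic = ic, type = res$type,
      min_R_E = res$min_R_E, max_R_E = res$max_R_E,
      min_R_I = res$min_R_I, max_R_I = res$max_R_I,
      period = res$period)
    ends[[length(ends) + 1]] <<- res$end
  }
  sweep_dir <- function(vals, label) {
    carry <- NULL
    for (v in vals) {
      pp <- set_param(p, free, v)
      # continuation from the previous attractor where available; fresh
      # starts (perturbed fixed point and a large kick) otherwise
      ics <- if (!is.null(carry)) list(cont = carry) else {
        fp <- ei_fixed_point(pp, s0 = ei_state())
        near <- if (!is.null(fp)) {
          s <- fp$state
          s[c("R_E", "R_I")] <- s[c("R_E", "R_I")] + 0.02
          s["V_E"] <- s["V_E"] + 0.1
          s
        } else ei_state()
        list(near_fp = near,
             kick = ei_state(R_E = 2, V_E = 1, R_I = 2, V_I = 1))
      }
      carried <- FALSE
      for (nm in names(ics)) {
        res <- run_one(pp, ics[[nm]])
        if (is.null(res)) next
        add_row(v, paste0(label, ":", nm), res)
        if (!carried) {
          carry <- res$end
          carried <- TRUE
        }
      }
      if (!carried) carry <- NULL
    }
  }
  sweep_dir(values, "fwd")
  sweep_dir(rev(values), "bwd")
  tab <- do.call(rbind, rows)
  # count distinct stable oscillatory branches per parameter value
  branch_count <- function(tab) vapply(values, function(v) {
    sub <- tab[tab$value == v & tab$type == "limit-cycle", , drop = FALSE]
    if (nrow(sub) < 2) return(nrow(sub))
    sig <- cbind(sub$max_R_I, sub$max_R_I - sub$min_R_I)
    groups <- rep(NA_integer_, nrow(sig))
    gid <- 0L
    for (i in seq_len(nrow(sig))) {
      placed <- FALSE
      if (gid > 0) for (gg in 1:gid) {
        ref <- sig[which(groups == gg)[1], ]
        if (all(abs(sig[i, ] - ref) < distinct_tol * pmax(1, abs(ref)))) {
          groups[i] <- gg; placed <- TRUE; break
        }
      }
      if (!placed) { gid <- gid + 1L; groups[i] <- gid }
    }
    gid
  }, numeric(1))
  find_windows <- function(n_branches) {
    co <- which(n_branches >= 2)
    if (length(co) == 0) return(NULL)
    breaks <- c(0, which(diff(co) > 1), length(co))
    do.call(rbind, lapply(seq_len(length(breaks) - 1), function(i) {
      idx <- co[(breaks[i] + 1):breaks[i + 1]]
      data.frame(lower = values[min(idx)], upper = values[max(idx)])
    }))
  }
  windows <- find_windows(branch_count(tab))
  # Re-verify "limit-cycle" rows near the window boundaries at doubled
  # horizon (continuing from each run's end state): a slowly escaping
  # transient can masquerade as a distinct oscillation and widen a
  # window by a grid step or two.
  if (!is.null(windows)) {
    step <- min(diff(values))
    bvals <- unique(unlist(lapply(seq_len(nrow(windows)), function(i)
      c(windows$lower[i] + c(-1, 0, 1) * step,
        windows$upper[i] + c(-1, 0, 1) * step))))
    redo <- which(tab$value %in% bvals & tab$type == "limit-cycle")
    for (i in redo) {
      pp <- set_param(p, free, tab$value[i])
      res2 <- run_one(pp, ends[[i]], horizon = 2 * T)
      if (is.null(res2)) next
      tab$type[i] <- res2$type
      tab$min_R_E[i] <- res2$min_R_E; tab$max_R_E[i] <- res2$max_R_E
      tab$min_R_I[i] <- res2$min_R_I; tab$max_R_I[i] <- res2$max_R_I
      tab$period[i] <- res2$period
      ends[[i]] <- res2$end
    }
    windows <- find_windows(branch_count(tab))
  }
  tab <- tab[order(tab$value), ]
  rownames(tab) <- NULL
  list(table = tab,
       n_branches = data.frame(value = values,
                               branches = branch_count(tab)),
       coexistence = windows)
}
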