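#' A published disproportionality row
#'
#' Holds the summary statistics a published signal table prints for one
#' drug-event pair -- the target-event count `a` and the 2-decimal ROR,
#' PRR and chi-square -- plus, optionally, the printed CI bounds, which are
#' held out of the search and used only for verification.
#'
#' @param a Target drug + target event count (>= 1).
#' @param ror,prr Printed point estimates (2 decimals).
#' @param chi2 Printed Pearson chi-square.
#' @param ror_low,ror_high Printed 95% CI bounds (optional; verification only).
#' @return An object of class `printed_row`.
#' @export
printed_row <- function(a, ror, prr, chi2, ror_low = NA_real_,
                        ror_high = NA_real_) {
  if (a < 1 || a != round(a)) stop("a must be a positive integer", call. = FALSE)
  if (ror <= 0 || prr <= 0 || chi2 < 0) {
    stop("ror and prr must be positive and chi2 nonnegative", call. = FALSE)
  }
  structure(list(a = as.integer(a), ror = ror, prr = prr, chi2 = chi2,
                 ror_low = ror_low, ror_high = ror_high),
            class = "printed_row")
}

#' Published glioma signal-table rows
#'
#' The transcribed published disproportionality rows (two databases, four
#' study drugs, three endpoints): case counts, ROR with 95% CI and signal
#' call, PRR with chi-square, IC with IC025 and EBGM with EB05, all at the
#' 2-decimal precision of the source tables. Shipped as a plain-text
#' fixture; used by the recovery oracle, the signal-rule check and the
#' IC-vs-EBGM arithmetic consistency check.
#'
#' @return Tibble with one row per published drug-event pair.
#' @export
glioma_reference_rows <- function() {
  df <- utils::read.delim(pv_extdata("glioma_reference_rows.tsv"), sep = "\t",
                          stringsAsFactors = FALSE)
  tibble::as_tibble(df)
}

# Vectorized bisection for a monotone function of d on [lo, hi].
# Returns the real d where fun(d) == target, clamped to the segment.
vbisect <- function(fun, lo, hi, target, increasing, iters = NULL) {
  flo <- fun(lo); fhi <- fun(hi)
  lo0 <- lo; hi0 <- hi
  if (is.null(iters)) {  # enough halvings for quarter-integer precision
    iters <- max(8L, ceiling(log2(max(hi - lo, 1) + 1)) + 3L)
  }
  for (i in seq_len(iters)) {
    mid <- (lo + hi) / 2
    fm <- fun(mid)
    go_right <- if (increasing) fm < target else fm > target
    lo[go_right] <- mid[go_right]
    hi[!go_right] <- mid[!go_right]
  }
  mid <- (lo + hi) / 2
  # clamp when the target is not bracketed by the segment: the crossing
  # lies beyond the end where the function approaches the target
  if (increasing) {
    mid[fhi < target] <- hi0[fhi < target]
    mid[flo > target] <- lo0[flo > target]
  } else {
    mid[flo < target] <- lo0[flo < target]
    mid[fhi > target] <- hi0[fhi > target]
  }
  mid
}

#' Reconstruct 2x2 tables from a published summary row
#'
#' Searches for all integer cell triples `(b, c, d)` that, together with the
#' printed `a`, reproduce the printed ROR and PRR to within `tol_ratio`
#' (half a printed unit by default) and the printed chi-square to within a
#' relative tolerance, accepting the Pearson statistic with or without
#' Yates continuity correction since published tables rarely state the
#' variant. The search is pruned analytically rather than looping blindly:
#' the printed ROR and PRR jointly pin the ratio `d/c` for every candidate
#' `b` (and thereby the admissible range of `b` itself), and the chi-square
#' then fixes the scale of `(c, d)` through a closed-form quadratic, so
#' only a thin shell of candidates is ever visited.
#'
#' For near-rare-event rows where the printed ROR and PRR coincide, the
#' admissible `b` is unbounded above and the solutions form a
#' one-parameter family along `b`; when the feasible range exceeds `n_b`
#' values it is probed log-uniformly (treating the unknown exposure margin
#' as a scale parameter) so the returned set spans the family.
#'
#' Solutions are returned in compressed form: consecutive `d` values that
#' all satisfy the constraints for a given `(b, c)` form one row with
#' bounds `d_min`/`d_max` and a representative `d_best` (the integer `d`
#' whose chi-square is closest to the printed value). The full solution
#' set is the union of these runs; [recovered_contains()] tests membership.
#'
#' @param row A [printed_row()].
#' @param b_max,c_max,d_max Upper search bounds for the three free cells.
#' @param tol_ratio Absolute match tolerance for the printed ROR and PRR.
#' @param tol_chi2_rel Relative match tolerance for the printed chi-square.
#' @param chi2_variant Which chi-square convention(s) to accept.
#' @param n_b Maximum number of `b` values to probe (use `Inf` to force
#'   exhaustive enumeration of the feasible range).
#' @param max_solutions Cap on returned rows (evenly thinned if exceeded).
#' @return Tibble of class `recovered_tables` with columns `a`, `b`, `c`,
#'   `d_min`, `d_max`, `d_best`, `n_d`, `variant`, `ror`, `prr`, `chi2`
#'   (statistics at `d_best`), `chi2_err` (relative), `ror_low`,
#'   `ror_high` (Woolf CI at `d_best`).
#' @export
recover_table <- function(row, b_max = 1e6, c_max = 1e6, d_max = 1e6,
                          tol_ratio = 0.005, tol_chi2_rel = 0.01,
                          chi2_variant = c("either", "plain", "yates"),
                          n_b = 500, max_solutions = 20000) {
  stopifnot(inherits(row, "printed_row"))
  chi2_variant <- match.arg(chi2_variant)
  a <- row$a
  eps <- 1e-12
  tol <- tol_ratio + 1e-9

  if (row$chi2 < 0.01) {
    chiL <- 0; chiH <- 0.01
  } else {
    chiL <- row$chi2 * (1 - tol_chi2_rel)
    chiH <- row$chi2 * (1 + tol_chi2_rel)
  }

  rho_bounds <- function(b) {
    lo <- pmax((row$ror - tol) * b / a, (row$prr - tol) * (a + b) / a - 1, eps)
    hi <- pmin((row$ror + tol) * b / a, (row$prr + tol) * (a + b) / a - 1)
    list(lo = lo, hi = hi)
  }

  # feasible b values form an interval (the gap hi - lo is concave in b)
  feas <- integer(0)
  for (start in seq(1, b_max, by = 2e5)) {
    bb <- start:min(start + 2e5 - 1, b_max)
    rb <- rho_bounds(bb)
    ok <- rb$lo <= rb$hi
    feas <- c(feas, bb[ok])
    if (length(feas) && !ok[length(ok)] && !all(ok)) break
  }
  if (!length(feas)) {
    stop("row unrecoverable at stated tolerances: no feasible exposure margin",
         call. = FALSE)
  }
  if (is.finite(n_b) && length(feas) > n_b) {
    grid <- exp(seq(log(min(feas)), log(max(feas)), length.out = n_b))
    feas <- unique(feas[findInterval(grid, feas, all.inside = TRUE)])
  }

  # stage 1: per-b window of candidate c from the chi-square quadratic
  # along the ray d = rho * c. On that ray the Pearson statistic increases
  # monotonically in c and saturates at (a*rho - b)^2 / ((a+b)*rho), so the
  # in-band c values form one interval whose ends are roots of a quadratic
  # (infinite when the band reaches the asymptote). The Yates-corrected
  # variant matches at slightly larger plain values, so the band's top is
  # widened when that variant is accepted; exact filtering happens in
  # stage 2.
  b <- feas
  rb <- rho_bounds(b)
  croot <- function(rho, chi) {
    # smallest positive c with chi2(c; d = rho*c) == chi (Inf beyond the
    # asymptote, 0 for chi <= 0)
    k <- (a * rho - b)^2
    asym <- k / ((a + b) * rho)
    A <- (1 + rho) * (k - chi * (a + b) * rho)
    B <- (a + b) * (k - chi * (1 + rho) * (a * rho + b))
    C <- -chi * (a + b) * (1 + rho) * a * b
    root <- (-B + sqrt(pmax(B^2 - 4 * A * C, 0))) / (2 * A)
    root[chi <= 0] <- 0
    root[chi >= asym] <- Inf
    root
  }
  top <- if (chi2_variant == "plain") chiH else chiH * 1.5
  cwin_lo <- pmin(croot(rb$lo, chiL), croot(rb$hi, chiL))
  cwin_hi <- pmax(croot(rb$lo, top), croot(rb$hi, top))
  ok <- is.finite(cwin_lo)
  b <- b[ok]
  cwin_lo <- pmax(floor(cwin_lo[ok]) - 2, 1)
  cwin_hi <- pmin(ceiling(pmin(cwin_hi[ok], cwin_lo + 2000)) + 2, c_max)
  width <- pmax(cwin_hi - cwin_lo + 1, 0)
  if (!length(b) || !sum(width)) {
    stop("row unrecoverable at stated tolerances", call. = FALSE)
  }

  # stage 2: expand (b, c) pairs; exact d-interval from ROR and PRR
  pb <- rep(b, width)
  rlo <- rep(rho_bounds(b)$lo, width)
  rhi <- rep(rho_bounds(b)$hi, width)
  pc <- unlist(lapply(seq_along(b), function(i) {
    seq.int(cwin_lo[i], length.out = width[i])
  }), use.names = FALSE)
  dlo <- ceiling(rlo * pc - 1e-9)
  dhi <- floor(rhi * pc + 1e-9)
  dlo <- pmax(dlo, 1)
  dhi <- pmin(dhi, d_max)
  keep <- dlo <= dhi
  pb <- pb[keep]; pc <- pc[keep]; dlo <- dlo[keep]; dhi <- dhi[keep]
  if (!length(pb)) stop("row unrecoverable at stated tolerances", call. = FALSE)

  variants <- switch(chi2_variant, either = c("plain", "yates"),
                     plain = "plain", yates = "yates")
  out <- list()
  for (variant in variants) {
    chi_fun <- if (variant == "plain") {
      function(d) pearson_chi2(a, pb_seg, pc_seg, d)
    } else {
      function(d) yates_chi2(a, pb_seg, pc_seg, d)
    }
    dstar <- pb * pc / a
    # monotone segments on each side of the independence point
    for (side in c("above", "below")) {
      if (side == "above") {
        seg_lo <- pmax(dlo, ceiling(dstar)); seg_hi <- dhi; increasing <- TRUE
      } else {
        seg_lo <- dlo; seg_hi <- pmin(dhi, floor(dstar)); increasing <- FALSE
      }
      sel <- seg_lo <= seg_hi
      if (!any(sel)) next
      pb_seg <- pb[sel]; pc_seg <- pc[sel]
      lo <- seg_lo[sel]; hi <- seg_hi[sel]
      rL <- vbisect(chi_fun, lo, hi, chiL, increasing)
      rH <- vbisect(chi_fun, lo, hi, chiH, increasing)
      if (increasing) {
        d1 <- ceiling(pmin(pmax(rL, lo), hi) - 1e-6)
        d2 <- floor(pmin(pmax(rH, lo), hi) + 1e-6)
      } else {
        d1 <- ceiling(pmin(pmax(rH, lo), hi) - 1e-6)
        d2 <- floor(pmin(pmax(rL, lo), hi) + 1e-6)
      }
      # tighten endpoints until the chi-square really is in band
      for (pass in 1:2) {
        bad1 <- d1 <= d2 & !(chi_fun(d1) >= chiL - 1e-9 & chi_fun(d1) <= chiH + 1e-9)
        d1[bad1] <- d1[bad1] + 1L
        bad2 <- d1 <= d2 & !(chi_fun(d2) >= chiL - 1e-9 & chi_fun(d2) <= chiH + 1e-9)
        d2[bad2] <- d2[bad2] - 1L
      }
      good <- d1 <= d2 &
        chi_fun(d1) >= chiL - 1e-9 & chi_fun(d1) <= chiH + 1e-9 &
        chi_fun(d2) >= chiL - 1e-9 & chi_fun(d2) <= chiH + 1e-9
      if (!any(good)) next
      pb_seg <- pb_seg[good]; pc_seg <- pc_seg[good]
      d1 <- d1[good]; d2 <- d2[good]
      rB <- vbisect(chi_fun, as.numeric(d1), as.numeric(d2),
                    row$chi2, increasing)
      dbest <- pmin(pmax(round(rB), d1), d2)
      out[[length(out) + 1]] <- tibble::tibble(
        b = pb_seg, c = pc_seg, d_min = d1, d_max = d2, d_best = dbest,
        variant = variant)
    }
  }
  if (!length(out)) {
    stop("row unrecoverable at stated tolerances", call. = FALSE)
  }
  sol <- do.call(rbind, out)
  sol <- sol[order(sol$b, sol$c, sol$d_min, sol$variant), ]
  sol <- sol[!duplicated(sol[c("b", "c", "d_min", "d_max", "variant")]), ]

  chi_of <- function(v, b, c, d) {
    ifelse(v == "plain", pearson_chi2(a, b, c, d), yates_chi2(a, b, c, d))
  }
  z <- stats::qnorm(0.975)
  sol <- tibble::as_tibble(sol)
  sol$a <- a
  sol$n_d <- sol$d_max - sol$d_min + 1L
  sol$ror <- a * sol$d_best / (sol$b * sol$c)
  sol$prr <- (a / (a + sol$b)) / (sol$c / (sol$c + sol$d_best))
  sol$chi2 <- chi_of(sol$variant, sol$b, sol$c, sol$d_best)
  sol$chi2_err <- abs(sol$chi2 - row$chi2) / max(row$chi2, 0.01)
  se <- sqrt(1 / a + 1 / sol$b + 1 / sol$c + 1 / sol$d_best)
  sol$ror_low <- sol$ror * exp(-z * se)
  sol$ror_high <- sol$ror * exp(z * se)
  sol <- sol[c("a", "b", "c", "d_min", "d_max", "d_best", "n_d", "variant",
               "ror", "prr", "chi2", "chi2_err", "ror_low", "ror_high")]
  if (nrow(sol) > max_solutions) {
    sol <- sol[unique(round(seq(1, nrow(sol), length.out = max_solutions))), ]
  }
  attr(sol, "printed") <- row
  class(sol) <- c("recovered_tables", class(sol))
  sol
}

#' Test whether a recovered solution set contains a specific table
#'
#' @param solutions Output of [recover_table()].
#' @param b,c,d Cell values to test (with the printed `a`).
#' @return Logical.
#' @export
recovered_contains <- function(solutions, b, c, d) {
  any(solutions$b == b & solutions$c == c &
        solutions$d_min <= d & solutions$d_max >= d)
}

# One representative table per probed b: the best run under the package's
# own (uncorrected Pearson) chi-square convention where one exists --
# published near-null rows are only consistent with that convention --
# falling back to Yates-only matches, tie-broken by chi-square error.
central_solutions <- function(solutions) {
  ord <- order(solutions$b, match(solutions$variant, c("plain", "yates")),
               solutions$chi2_err)
  sol <- solutions[ord, ]
  sol[!duplicated(sol$b), ]
}

#' Verify printed confidence intervals against recovered tables
#'
#' Recomputes the Woolf 95% CI of the ROR on each recovered table (one
#' representative per probed exposure margin `b`), rounds to the printed
#' precision and compares against the printed bounds. Because a published
#' row constrains but does not uniquely determine the table, the verdict
#' reports the vote share of each rounded bound across the solution family
#' together with the spread of the unrounded bounds.
#'
#' @param row A [printed_row()] with `ror_low`/`ror_high` filled in.
#' @param solutions Output of [recover_table()] for that row.
#' @return An object of class `pv_ci_verdict`: a list with one element per
#'   bound carrying `printed`, `modal` (modal recomputed rounded bound),
#'   `share` (its vote share), `agrees` (modal == printed), `all_agree`,
#'   `spread` (range of unrounded bounds) and the vote table.
#' @export
verify_printed_ci <- function(row, solutions) {
  stopifnot(inherits(row, "printed_row"))
  if (!nrow(solutions)) stop("solutions must be nonempty", call. = FALSE)
  cen <- central_solutions(solutions)
  verdict_for <- function(values, printed) {
    rounded <- round(values, 2)
    votes <- sort(table(rounded), decreasing = TRUE)
    modal <- as.numeric(names(votes)[1])
    list(printed = printed, modal = modal,
         share = as.numeric(votes[1]) / length(rounded),
         agrees = isTRUE(all.equal(modal, printed)),
         all_agree = length(votes) == 1 &&
           isTRUE(all.equal(modal, printed)),
         spread = diff(range(values)), votes = votes)
  }
  out <- list(low = verdict_for(cen$ror_low, row$ror_low),
              high = verdict_for(cen$ror_high, row$ror_high),
              n_solutions = nrow(cen),
              b_range = range(cen$b),
              variants = table(cen$variant))
  class(out) <- "pv_ci_verdict"
  out
}

#' @export
print.pv_ci_verdict <- function(x, ...) {
  fmt <- function(v, name) {
    cat(sprintf("  %s bound: printed %.2f, modal recomputed %.2f (share %.0f%%), %s; unrounded spread %.4f\n",
                name, v$printed, v$modal, 100 * v$share,
                if (isTRUE(v$agrees)) "agrees" else "DISAGREES", v$spread))
  }
  cat(sprintf("<CI verification over %d recovered tables, b in [%d, %d]>\n",
              x$n_solutions, x$b_range[1], x$b_range[2]))
  fmt(x$low, "lower"); fmt(x$high, "upper")
  invisible(x)
}
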