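## Bounded-variable revised simplex for the flux balance problems:
##
##   maximize  c'x   subject to  A x = b,  lb <= x <= ub
##
## Bounds are handled natively (nonbasic variables sit at a bound), which
## keeps the working dimension at the number of balance rows. Two phases
## with artificial variables; Dantzig pricing with a Bland's-rule fallback
## against cycling on the (heavily degenerate) metabolic polytopes;
## periodic refactorization of the basis inverse against numerical drift.

SIMPLEX_TOL <- 1e-9

simplex_box <- function(A, b, lb, ub, obj, maximize = TRUE,
                        tol = SIMPLEX_TOL, max_iter = NULL) {
  m <- nrow(A); n <- ncol(A)
  if (any(lb > ub + 1e-12)) return(list(status = "infeasible"))
  cc_user <- if (maximize) obj else -obj
  if (m == 0L) {   # no balance rows: each variable sits at its best bound
    v <- ifelse(cc_user > 0, ub, lb)
    v[cc_user == 0] <- lb[cc_user == 0]
    if (any(!is.finite(v) & cc_user != 0)) return(list(status = "unbounded"))
    v[!is.finite(v)] <- 0
    val <- sum(cc_user * v)
    return(list(status = "optimal", x = v,
                value = if (maximize) val else -val))
  }
  start <- ifelse(is.finite(lb), lb, ifelse(is.finite(ub), ub, 0))
  stat <- ifelse(is.finite(lb), -1L, ifelse(is.finite(ub), 1L, -1L))
  x <- c(start, 0 * seq_len(m))
  r <- b - as.vector(A %*% start)
  sgn <- ifelse(r >= 0, 1, -1)
  Aall <- cbind(A, diag(sgn, m))
  lbx <- c(lb, rep(0, m)); ubx <- c(ub, rep(Inf, m))
  x[n + seq_len(m)] <- abs(r)
  nall <- n + m
  state <- list(basic = n + seq_len(m), statx = c(stat, rep(0L, m)),
                x = x, Binv = diag(sgn, m))
  if (is.null(max_iter)) max_iter <- 2000L + 200L * (n + m)

  refactor <- function(st) {
    Binv <- tryCatch(solve(Aall[, st$basic, drop = FALSE]),
                     error = function(e) NULL)
    if (is.null(Binv)) return(NULL)
    nb <- setdiff(seq_len(nall), st$basic)
    st$x[st$basic] <- as.vector(
      Binv %*% (b - Aall[, nb, drop = FALSE] %*% st$x[nb]))
    st$Binv <- Binv
    st
  }

  run_phase <- function(cc, st) {
    it <- 0L; degen <- 0L; bland <- FALSE
    repeat {
      it <- it + 1L
      if (it > max_iter) return(list(status = "iteration_limit"))
      if (it %% 250L == 0L) {
        st2 <- refactor(st)
        if (is.null(st2)) return(list(status = "singular"))
        st <- st2
      }
      basic <- st$basic; statx <- st$statx; x <- st$x; Binv <- st$Binv
      y <- as.vector(crossprod(Binv, cc[basic]))
      d <- cc - as.vector(crossprod(Aall, y))
      d[basic] <- 0
      movable <- statx != 0L & lbx < ubx
      viol <- numeric(nall)
      lo <- movable & statx == -1L & d > tol
      hi <- movable & statx == 1L & d < -tol
      viol[lo] <- d[lo]; viol[hi] <- -d[hi]
      cand <- which(viol > 0)
      if (!length(cand)) { st$status <- "optimal"; return(st) }
      e <- if (bland) cand[1L] else cand[which.max(viol[cand])]
      sig <- if (statx[e] == -1L) 1 else -1
      w <- as.vector(Binv %*% Aall[, e])
      step <- -w * sig          # movement of basic vars per unit entering
      ratio <- rep(Inf, m)
      up <- step > tol; dn <- step < -tol
      ratio[up] <- (ubx[basic[up]] - x[basic[up]]) / step[up]
      ratio[dn] <- (lbx[basic[dn]] - x[basic[dn]]) / step[dn]
      ratio[ratio < 0] <- 0     # degenerate: already at the blocking bound
      flip <- ubx[e] - lbx[e]
      tmax <- min(ratio, flip)
      if (!is.finite(tmax)) return(list(status = "unbounded"))
      if (tmax <= flip - tol || (is.finite(flip) == FALSE)) {
        near <- which(ratio <= tmax + tol)
        leave <- if (bland) near[which.min(basic[near])]
        else near[which.max(abs(step[near]))]   # largest pivot for stability
      } else leave <- 0L
      degen <- if (tmax < tol) degen + 1L else 0L
      bland <- degen > 50L
      x[basic] <- x[basic] + step * tmax
      x[e] <- x[e] + sig * tmax
      if (leave == 0L) {
        statx[e] <- -statx[e]   # bound flip, basis unchanged
        st$statx <- statx; st$x <- x
        next
      }
      lv <- basic[leave]
      statx[lv] <- if (step[leave] > 0) 1L else -1L
      x[lv] <- if (statx[lv] == 1L) ubx[lv] else lbx[lv]
      statx[e] <- 0L
      basic[leave] <- e
      piv <- w[leave]
      if (abs(piv) < 1e-11) {
        st$basic <- basic; st$statx <- statx; st$x <- x
        st2 <- refactor(st)
        if (is.null(st2)) return(list(status = "singular"))
        st <- st2
        next
      }
      fac <- w / piv
      fac[leave] <- 1 - 1 / piv
      Binv <- Binv - outer(fac, Binv[leave, ])
      st$basic <- basic; st$statx <- statx; st$x <- x; st$Binv <- Binv
    }
  }

  ## phase 1: drive the artificials out
  p1 <- run_phase(c(rep(0, n), rep(-1, m)), state)
  if (!identical(p1$status, "optimal")) return(list(status = "infeasible"))
  if (sum(p1$x[n + seq_len(m)]) > 1e-6 * max(1, max(abs(b))))
    return(list(status = "infeasible"))
  ubx[n + seq_len(m)] <- 0
  p1$x[n + seq_len(m)] <- pmin(p1$x[n + seq_len(m)], 0)
  p1$status <- NULL
  p2 <- run_phase(c(cc_user, rep(0, m)), p1)
  if (!identical(p2$status, "optimal"))
    return(list(status = if (identical(p2$status, "unbounded")) "unbounded"
                else p2$status))
  v <- pmin(pmax(p2$x[seq_len(n)], lb), ub)
  val <- sum(cc_user * v)
  list(status = "optimal", x = v, value = if (maximize) val else -val)
}
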