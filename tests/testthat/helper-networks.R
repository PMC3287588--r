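## Shared fixtures and the brute-force LP oracle.

## canonical fixture, built once per test run
core_fixture <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- generate_core_network()
    cache
  }
})

## linear uptake -> conversion -> drain chain used in several unit tests
chain_model <- function(uptake_cap = 10) {
  mets <- rbind(metabolite("a_e", is_boundary = TRUE),
                metabolite("a_c"), metabolite("b_c"))
  rxns <- list(
    reaction("EX_a", c(a_e = -1), reversible = TRUE, lb = -uptake_cap, ub = 0,
             kind = "exchange"),
    reaction("t_a", c(a_e = -1, a_c = 1), kind = "transport"),
    reaction("conv", c(a_c = -1, b_c = 1)),
    reaction("dm_b", c(b_c = -1), kind = "biomass_drain")
  )
  phyco_model(mets, rxns, biomass_components = "dm_b")
}

## Exhaustive vertex enumeration for max/min c'v s.t. S v = 0, lb<=v<=ub.
## Vertices of the box-constrained flux polytope have at least
## n - rank(S) variables pinned to a bound; enumerate all such pinnings.
vertex_enum_optimum <- function(S, lb, ub, obj, maximize = TRUE) {
  n <- ncol(S)
  rk <- if (nrow(S)) qr(S)$rank else 0L
  k <- n - rk
  best <- NA_real_
  check <- function(v) {
    if (any(v < lb - 1e-7) || any(v > ub + 1e-7)) return()
    if (nrow(S) && max(abs(S %*% v)) > 1e-6) return()
    val <- sum(obj * v)
    if (is.na(best) || (maximize && val > best) || (!maximize && val < best))
      best <<- val
  }
  if (k == 0L) {
    v <- tryCatch(qr.solve(S, rep(0, nrow(S))), error = function(e) NULL)
    if (!is.null(v)) check(v)
  } else {
    sets <- utils::combn(n, k, simplify = FALSE)
    for (fixed in sets) {
      free <- setdiff(seq_len(n), fixed)
      Sf <- S[, free, drop = FALSE]
      grid <- expand.grid(rep(list(c(FALSE, TRUE)), k))
      for (g in seq_len(nrow(grid))) {
        vfix <- ifelse(unlist(grid[g, ]), ub[fixed], lb[fixed])
        rhs <- -S[, fixed, drop = FALSE] %*% vfix
        vf <- tryCatch(qr.solve(Sf, rhs), error = function(e) NULL)
        if (is.null(vf)) next
        v <- numeric(n)
        v[fixed] <- vfix; v[free] <- vf
        check(v)
      }
    }
  }
  best
}

## run both the solver and the oracle on a model and compare
expect_matches_vertex_oracle <- function(model, objective, sense = "max") {
  S <- stoichiometric_matrix(model)
  lb <- vapply(model$reactions[colnames(S)], `[[`, 0, "lb")
  ub <- vapply(model$reactions[colnames(S)], `[[`, 0, "ub")
  obj <- as.numeric(colnames(S) == objective)
  ref <- vertex_enum_optimum(S, lb, ub, obj, maximize = sense == "max")
  fd <- solve_fba(model, objective, sense, parsimonious = FALSE)
  if (is.na(ref)) {
    expect_equal(fd$status, "infeasible")
  } else {
    expect_equal(fd$status, "optimal")
    expect_equal(fd$objective_value, ref,
                 tolerance = 1e-8 * max(1, abs(ref)))
  }
  invisible(fd)
}

## steady-state check asserted across the FBA tests
expect_steady_state <- function(fd, model) {
  expect_equal(fd$status, "optimal")
  S <- stoichiometric_matrix(model)
  resid <- max(abs(S %*% fd$fluxes[colnames(S)]))
  expect_lte(resid, 1e-6 * max(1, max(abs(fd$fluxes))))
  invisible(resid)
}

## small random compartment-free networks (<= 8 reactions) for the oracle
random_small_model <- function(seed) {
  set.seed(seed)
  n_int <- sample(2:5, 1)
  n_mets <- sample(2:4, 1)
  mets <- do.call(rbind, lapply(seq_len(n_mets), function(i)
    metabolite(paste0("m", i, "_c"))))
  mets <- rbind(mets, metabolite("s_e", is_boundary = TRUE))
  rxns <- list(reaction("EX_s", c(s_e = -1), reversible = TRUE,
                        lb = -sample(1:10, 1), ub = 0, kind = "exchange"),
               reaction("up", c(s_e = -1, m1_c = 1), kind = "transport"))
  pick1 <- function(x) x[sample.int(length(x), 1)]
  for (j in seq_len(n_int)) {
    from <- sample(n_mets, 1)
    to <- pick1(setdiff(seq_len(n_mets), from))
    st <- stats::setNames(c(-sample(1:2, 1), sample(1:2, 1)),
                          paste0("m", c(from, to), "_c"))
    rev <- runif(1) < 0.3
    rxns[[length(rxns) + 1L]] <- reaction(paste0("r", j), st,
                                          reversible = rev,
                                          lb = if (rev) -50 else 0, ub = 50)
  }
  drain_met <- paste0("m", sample(n_mets, 1), "_c")
  rxns[[length(rxns) + 1L]] <- reaction("dm", stats::setNames(-1, drain_met),
                                        kind = "biomass_drain")
  phyco_model(mets, rxns, biomass_components = "dm")
}
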