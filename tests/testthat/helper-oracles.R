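# Independent brute-force oracles used to validate the package's
# implementations. Deliberately naive: enumeration and loops, no shared
# code with the implementation paths they check.

# maximize obj'x subject to A x = b, lb <= x <= ub, by enumerating candidate
# vertices: fix (n - rank(A)) variables at a bound, solve for the rest
oracle_lp <- function(obj, A, b, lb, ub) {
  A <- as.matrix(A)
  n <- ncol(A)
  k <- n - qr(A)$rank
  best <- -Inf
  feasible <- FALSE
  try_point <- function(x) {
    if (max(abs(A %*% x - b)) > 1e-7) return()
    if (all(x >= lb - 1e-8) && all(x <= ub + 1e-8)) {
      feasible <<- TRUE
      best <<- max(best, sum(obj * x))
    }
  }
  combos <- if (k == 0) list(integer(0)) else utils::combn(n, k, simplify = FALSE)
  for (fixed in combos) {
    rest <- setdiff(seq_len(n), fixed)
    if (length(fixed) == 0L) {
      sol <- tryCatch(qr.solve(A, b), error = function(e) NULL)
      if (!is.null(sol)) try_point(as.numeric(sol))
      next
    }
    choice <- expand.grid(rep(list(1:2), length(fixed)))
    for (gi in seq_len(nrow(choice))) {
      xf <- ifelse(unlist(choice[gi, ]) == 1, lb[fixed], ub[fixed])
      Ar <- A[, rest, drop = FALSE]
      if (length(rest) && qr(Ar)$rank < length(rest)) next
      sol <- tryCatch(qr.solve(Ar, b - A[, fixed, drop = FALSE] %*% xf),
                      error = function(e) NULL)
      if (is.null(sol)) next
      x <- numeric(n)
      x[fixed] <- xf
      x[rest] <- as.numeric(sol)
      try_point(x)
    }
  }
  list(feasible = feasible, objective = best)
}

# random steady-state network for the LP oracle comparison
random_lp_network <- function(n_max = 8) {
  n <- sample(3:n_max, 1)
  m <- sample(2:(n - 1), 1)
  A <- matrix(sample(c(-1, 0, 1, 2), m * n, replace = TRUE,
                     prob = c(0.3, 0.3, 0.3, 0.1)), m, n)
  lb <- round(runif(n, -10, 2), 1)
  ub <- lb + round(runif(n, 0, 12), 1)
  if (runif(1) < 0.7) { lb <- pmin(lb, 0); ub <- pmax(ub, 0) }
  b <- if (runif(1) < 0.8) rep(0, m) else round(A %*% runif(n, -1, 1), 1)
  obj <- round(runif(n, -2, 2), 1)
  list(obj = obj, A = A, b = as.numeric(b), lb = lb, ub = ub)
}

# naive fitness-thresholded PR-AUC: explicit loops over unique thresholds,
# positive class = essential, called-positive = fitness <= t
oracle_pr_auc <- function(fitness, essential) {
  ths <- sort(unique(fitness))
  rec <- c(0)
  prec <- c(1)
  npos <- sum(essential)
  for (t in ths) {
    called <- fitness <= t
    tp <- sum(called & essential)
    rec <- c(rec, tp / npos)
    prec <- c(prec, tp / sum(called))
  }
  auc <- 0
  for (i in seq_len(length(rec) - 1))
    auc <- auc + (rec[i + 1] - rec[i]) * (prec[i + 1] + prec[i]) / 2
  auc
}

# breadth-first search on an edge list; returns hop counts from src
oracle_bfs <- function(edges, nodes, src) {
  dist <- stats::setNames(rep(Inf, length(nodes)), nodes)
  if (!src %in% nodes) return(dist)
  dist[src] <- 0
  frontier <- src
  while (length(frontier)) {
    nxt <- character(0)
    for (v in frontier) {
      nb <- c(edges$to[edges$from == v], edges$from[edges$to == v])
      nb <- nb[dist[nb] == Inf]
      dist[nb] <- dist[v] + 1
      nxt <- c(nxt, nb)
    }
    frontier <- unique(nxt)
  }
  dist
}

# union-find over |pearson correlation| > threshold, brute-force pairwise
oracle_corr_components <- function(x, corr_min = 0.99) {
  p <- ncol(x)
  parent <- seq_len(p)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  for (i in seq_len(p - 1)) for (j in (i + 1):p) {
    r <- suppressWarnings(stats::cor(x[, i], x[, j]))
    if (!is.na(r) && abs(r) > corr_min) {
      ri <- find(i); rj <- find(j)
      if (ri != rj) parent[ri] <- rj
    }
  }
  roots <- vapply(seq_len(p), find, integer(1))
  split(colnames(x), roots)
}

# random bipartite metabolite-reaction style graph as an edge list
random_bipartite_edges <- function(n_met = 8, n_rxn = 8, p_edge = 0.25) {
  mets <- paste0("m", seq_len(n_met))
  rxns <- paste0("r", seq_len(n_rxn))
  pick <- which(matrix(runif(n_met * n_rxn) < p_edge, n_met, n_rxn),
                arr.ind = TRUE)
  data.frame(from = mets[pick[, 1]], to = rxns[pick[, 2]],
             stringsAsFactors = FALSE)
}

# a tiny hand-checked linear model: EX_A (uptake) -> transport -> biomass
tiny_chain_model <- function(ex_lb = -10) {
  metabolic_model(
    id = "chain",
    metabolites = data.frame(id = c("A_e", "A_c"), name = c("A_e", "A_c"),
                             compartment = c("e", "c")),
    reactions = data.frame(
      id = c("EX_A", "T_A", "BIO"),
      name = c("EX_A", "T_A", "BIO"),
      lower_bound = c(ex_lb, -1000, 0),
      upper_bound = c(1000, 1000, 1000),
      gene_reaction_rule = c("", "gT", "gB")),
    stoichiometry = list(EX_A = c(A_e = -1),
                         T_A = c(A_e = -1, A_c = 1),
                         BIO = c(A_c = -1)),
    biomass_reaction_id = "BIO")
}

# default toy fixture shared across tests (built once per test run)
toy_fixture <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- build_toy_gem(toy_gem_config())
    cache
  }
})
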