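test_that("FBA solves the hand-checked uptake chain", {
  m <- tiny_chain_model(ex_lb = -10)
  s <- solve_fba(m)
  expect_equal(s$status, "optimal")
  expect_equal(s$objective_value, 10, tolerance = 1e-6)

  # no uptake allowed: zero growth
  closed <- tiny_chain_model(ex_lb = 0)
  expect_equal(solve_fba(closed)$objective_value, 0, tolerance = 1e-9)
})

test_that("FBA matches vertex enumeration on random bounded networks", {
  set.seed(101)
  for (trial in 1:60) {
    net <- random_lp_network()
    o <- oracle_lp(net$obj, net$A, net$b, net$lb, net$ub)
    s <- lp_solve(net$obj, net$A, net$b, net$lb, net$ub, maximize = TRUE)
    if (!o$feasible) {
      expect_equal(s$status, "infeasible")
    } else {
      expect_equal(s$status, "optimal")
      expect_equal(s$objective, o$objective, tolerance = 1e-6)
    }
  }
})

test_that("optimal solutions satisfy steady state and bounds", {
  toy <- toy_fixture()
  m <- apply_medium(toy$model, toy$medium, carbon_metabolite = "carb1_e")
  for (sol in list(solve_fba(m), solve_pfba(m))) {
    expect_equal(sol$status, "optimal")
    v <- sol$fluxes[m$reactions$id]
    expect_lt(max(abs(as.matrix(m$S) %*% v)), 1e-6)
    expect_true(all(v >= m$reactions$lower_bound - 1e-6))
    expect_true(all(v <= m$reactions$upper_bound + 1e-6))
  }
})

test_that("pFBA keeps the biomass optimum and never carries more total flux", {
  # two routes to biomass of equal yield: a 2-reaction and a 3-reaction one;
  # parsimony must put all flux on the short route
  m <- metabolic_model(
    id = "tworoute",
    metabolites = data.frame(id = c("A_e", "A_c", "B_c", "P_c"),
                             name = c("A_e", "A_c", "B_c", "P_c"),
                             compartment = c("e", "c", "c", "c")),
    reactions = data.frame(
      id = c("EX_A", "T_A", "SHORT", "LONG1", "LONG2", "BIO"),
      name = c("EX_A", "T_A", "SHORT", "LONG1", "LONG2", "BIO"),
      lower_bound = c(-10, 0, 0, 0, 0, 0),
      upper_bound = c(1000, 1000, 1000, 1000, 1000, 1000),
      gene_reaction_rule = ""),
    stoichiometry = list(
      EX_A = c(A_e = -1),
      T_A = c(A_e = -1, A_c = 1),
      SHORT = c(A_c = -1, P_c = 1),
      LONG1 = c(A_c = -1, B_c = 1),
      LONG2 = c(B_c = -1, P_c = 1),
      BIO = c(P_c = -1)),
    biomass_reaction_id = "BIO")
  fba <- solve_fba(m)
  p <- solve_pfba(m)
  expect_equal(p$objective_value, fba$objective_value, tolerance = 1e-6)
  expect_equal(unname(p$fluxes["LONG1"]), 0, tolerance = 1e-9)
  expect_equal(unname(p$fluxes["SHORT"]), 10, tolerance = 1e-6)
  # oracle: the two route-vertices of the optimal face
  short_vertex <- sum(abs(c(-10, 10, 10, 0, 0, 10)))
  long_vertex <- sum(abs(c(-10, 10, 0, 10, 10, 10)))
  expect_lte(p$total_flux, min(short_vertex, long_vertex) + 1e-6)
  expect_lte(p$total_flux, sum(abs(fba$fluxes)) + 1e-6)

  # a detached bounded reversible 2-cycle carries no parsimonious flux
  m2 <- metabolic_model(
    id = "cycle",
    metabolites = data.frame(id = c("A_e", "A_c", "X_c", "Y_c"),
                             name = c("A_e", "A_c", "X_c", "Y_c"),
                             compartment = c("e", "c", "c", "c")),
    reactions = data.frame(
      id = c("EX_A", "T_A", "BIO", "CYC1", "CYC2"),
      name = c("EX_A", "T_A", "BIO", "CYC1", "CYC2"),
      lower_bound = c(-10, 0, 0, -50, -50),
      upper_bound = c(1000, 1000, 1000, 50, 50),
      gene_reaction_rule = ""),
    stoichiometry = list(
      EX_A = c(A_e = -1),
      T_A = c(A_e = -1, A_c = 1),
      BIO = c(A_c = -1),
      CYC1 = c(X_c = -1, Y_c = 1),
      CYC2 = c(Y_c = -1, X_c = 1)),
    biomass_reaction_id = "BIO")
  p2 <- solve_pfba(m2)
  expect_equal(unname(p2$fluxes["CYC1"]), 0, tolerance = 1e-9)
  expect_equal(unname(p2$fluxes["CYC2"]), 0, tolerance = 1e-9)
})

test_that("knockout propagation disables exactly the GPR-false reactions", {
  toy <- toy_fixture()
  m <- toy$model
  # OR survives a single member knockout
  ko <- apply_knockout(m, "isoA_1")
  expect_equal(ko$reactions$upper_bound[ko$reactions$id == "ISO_1"], 1000)
  # both members disable the reaction
  ko2 <- apply_knockout(m, c("isoA_1", "isoB_1"))
  expect_equal(ko2$reactions$upper_bound[ko2$reactions$id == "ISO_1"], 0)
  expect_equal(ko2$reactions$lower_bound[ko2$reactions$id == "ISO_1"], 0)
  # locality: only reactions mentioning the knocked-out genes change
  changed <- which(ko2$reactions$upper_bound != m$reactions$upper_bound |
                     ko2$reactions$lower_bound != m$reactions$lower_bound)
  for (j in changed)
    expect_true(any(c("isoA_1", "isoB_1") %in% gpr_genes(m$gpr[[j]])))
  # the input model is not mutated
  expect_equal(m$reactions$upper_bound[m$reactions$id == "ISO_1"], 1000)
  expect_error(apply_knockout(m, "no_such_gene"), "unknown gene")
})

test_that("disabling additional reactions never increases the optimum", {
  toy <- toy_fixture()
  m <- apply_medium(toy$model, toy$medium, carbon_metabolite = "carb1_e")
  base <- solve_fba(m)$objective_value
  set.seed(42)
  genes <- sample(m$genes, 8)
  prev <- base
  knocked <- character()
  for (g in genes) {
    knocked <- c(knocked, g)
    s <- solve_fba(apply_knockout(m, knocked))
    mu <- if (s$status == "optimal") s$objective_value else 0
    expect_lte(mu, prev + 1e-6)
    prev <- mu
  }
})

test_that("knockout grid covers the grid with wild-type rows and reuses no-op knockouts", {
  toy <- toy_fixture()
  genes <- c("tr_carb1", "cat_carb2_1", "isoB_1", "glyA")
  carbons <- toy$carbons[1:2, ]
  grid <- knockout_grid(toy$model, genes, carbons,
                        scenario = scenario_spec(medium = toy$medium))
  expect_equal(nrow(grid), (length(genes) + 1) * 2)
  wt <- grid[grid$gene == "WT", ]
  expect_true(all(wt$grows))
  # a gene acting only on carbon 1 blocks growth there and nowhere else
  r <- grid[grid$gene == "tr_carb1", ]
  expect_false(r$grows[r$carbon == "carb1"])
  expect_true(r$grows[r$carbon == "carb2"])
  # a knockout that touches nothing active reproduces wild-type biomass
  r2 <- grid[grid$gene == "isoB_1", ]
  expect_equal(r2$biomass_flux, wt$biomass_flux, tolerance = 1e-9)
})

test_that("unconditional essentials are genes no environment can rescue", {
  # vitamin-analogue chain with an importable product: rescued, hence
  # conditional; a sole biomass-producing gene with no substitute: essential
  m <- metabolic_model(
    id = "uncond",
    metabolites = data.frame(id = c("A_e", "A_c", "V_e", "V_c"),
                             name = c("A_e", "A_c", "V_e", "V_c"),
                             compartment = c("e", "c", "e", "c")),
    reactions = data.frame(
      id = c("EX_A", "T_A", "EX_V", "T_V", "VSYN", "BIO"),
      name = c("EX_A", "T_A", "EX_V", "T_V", "VSYN", "BIO"),
      lower_bound = c(-10, 0, 0, 0, 0, 0),
      upper_bound = c(1000, 1000, 1000, 1000, 1000, 1000),
      gene_reaction_rule = c("", "gT", "", "", "gV", "gB")),
    stoichiometry = list(
      EX_A = c(A_e = -1),
      T_A = c(A_e = -1, A_c = 1),
      EX_V = c(V_e = -1),
      T_V = c(V_e = -1, V_c = 1),
      VSYN = c(A_c = -1, V_c = 1),
      BIO = c(A_c = -1, V_c = -1)),
    biomass_reaction_id = "BIO")
  ess <- find_unconditional_essentials(m)
  expect_true("gB" %in% ess)   # biomass reaction itself
  expect_true("gT" %in% ess)   # the only route for A
  expect_false("gV" %in% ess)  # import rescues the synthesis knockout
  # genes absent from all GPRs are never essential
  expect_false(any(!ess %in% m$genes))

  toy <- toy_fixture()
  expect_length(find_unconditional_essentials(toy$model), 0)
})
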