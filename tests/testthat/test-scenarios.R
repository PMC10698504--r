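test_that("applying a medium closes exchanges then opens the stated components", {
  toy <- toy_fixture()
  m <- apply_medium(toy$model, toy$medium, carbon_metabolite = "carb1_e")
  rx <- m$reactions
  expect_equal(rx$lower_bound[rx$id == "EX_nut1_e"], -1000)
  expect_equal(rx$lower_bound[rx$id == "EX_carb1_e"], -10)
  other_ex <- rx$is_exchange & !rx$id %in% c("EX_nut1_e", "EX_carb1_e")
  expect_true(all(rx$lower_bound[other_ex] == 0))

  # an empty medium closes everything: the wild type cannot grow
  closed <- apply_medium(toy$model, medium_spec())
  expect_lt(solve_fba(closed)$objective_value, 0.001)

  # carbon bound wins over a colliding base-component bound
  med <- medium_spec(components = c(EX_nut1_e = -1000, EX_carb1_e = -1000),
                     carbon_uptake_bound = -10)
  expect_message(m2 <- apply_medium(toy$model, med,
                                    carbon_metabolite = "carb1_e"),
                 "takes precedence")
  expect_equal(m2$reactions$lower_bound[m2$reactions$id == "EX_carb1_e"], -10)

  expect_error(apply_medium(toy$model,
                            medium_spec(components = c(EX_nope = -1))),
               "not in model")
})

test_that("supplementing a vitamin rescues its biosynthesis knockout", {
  toy <- toy_fixture()
  scen <- scenario_spec(medium = toy$medium)
  base <- apply_scenario(toy$model, scen, carbon_metabolite = "carb1_e")
  ko <- apply_knockout(base, "vit_1_1")
  expect_lt(solve_fba(ko)$objective_value, 0.001)

  # extracellular mode opens the existing exchange
  supp <- add_supplement(base, "vit1_e", "extracellular")
  expect_gte(solve_fba(apply_knockout(supp, "vit_1_1"))$objective_value, 0.001)

  # intracellular mode creates an uptake-only exchange on the cytoplasmic
  # species, working even without a transporter
  supp2 <- add_supplement(base, "vit2_c", "intracellular")
  ex_id <- "EX_vit2_c_supplement"
  expect_true(ex_id %in% supp2$reactions$id)
  expect_equal(supp2$reactions$upper_bound[supp2$reactions$id == ex_id], 0)
  expect_gte(solve_fba(apply_knockout(supp2, "vit_2_1"))$objective_value, 0.001)

  # supplementing twice is a no-op; a metabolite without exchange demands
  # intracellular mode
  supp3 <- add_supplement(supp, "vit1_e", "extracellular")
  expect_equal(supp3$reactions, supp$reactions)
  expect_error(add_supplement(base, "cx_c", "extracellular"),
               "intracellular")
})

test_that("irreversibilizing the bypass flips the pathway knockout to lethal", {
  toy <- toy_fixture()
  base <- apply_scenario(toy$model, scenario_spec(medium = toy$medium),
                         carbon_metabolite = "carb1_e")
  # with the reversible bypass the serine-analogue knockout still grows
  expect_gte(solve_fba(apply_knockout(base, "serA_1"))$objective_value, 0.001)
  fixed <- set_irreversible(base, "BYP")
  expect_lt(solve_fba(apply_knockout(fixed, "serA_1"))$objective_value, 0.001)
  # wild type is unaffected
  expect_gte(solve_fba(fixed)$objective_value, 0.001)
  # already-irreversible reactions are untouched
  again <- set_irreversible(fixed, "BYP")
  expect_equal(again$reactions, fixed$reactions)
  expect_error(set_irreversible(base, "NOPE"), "unknown reaction")
})

test_that("isoenzyme reassignment removes the in-silico rescue", {
  toy <- toy_fixture()
  base <- apply_scenario(toy$model, scenario_spec(medium = toy$medium),
                         carbon_metabolite = "carb1_e")
  expect_gte(solve_fba(apply_knockout(base, "isoA_1"))$objective_value, 0.001)
  re <- reassign_isoenzyme(base, "isoA_1", "ISO_1")
  expect_equal(re$reactions$gene_reaction_rule[re$reactions$id == "ISO_1"],
               "isoA_1")
  expect_lt(solve_fba(apply_knockout(re, "isoA_1"))$objective_value, 0.001)
  # the silent partner's knockout now has no effect at all
  expect_gte(solve_fba(apply_knockout(re, "isoB_1"))$objective_value, 0.001)
  # reassigning an already-single rule is a no-op; unknown gene errors
  re2 <- reassign_isoenzyme(re, "isoA_1", "ISO_1")
  expect_equal(re2$reactions, re$reactions)
  expect_error(reassign_isoenzyme(base, "glyA", "ISO_1"),
               "does not appear")
})

test_that("strain gene removal deletes orphaned reactions entirely", {
  toy <- toy_fixture()
  m <- remove_strain_genes(toy$model, "glyA")
  expect_false("GLY_BYP" %in% m$reactions$id)
  expect_false("glyA" %in% m$genes)
  expect_equal(ncol(m$S), nrow(m$reactions))
  # one member of an OR pair leaves the reaction in place
  m2 <- remove_strain_genes(toy$model, "isoB_1")
  expect_true("ISO_1" %in% m2$reactions$id)
  # unknown genes are skipped with a message; empty list is identity
  expect_message(m3 <- remove_strain_genes(toy$model, "nope"), "skipping")
  expect_equal(remove_strain_genes(toy$model, character()), toy$model)
})

test_that("fix_flux overwrites bounds exactly", {
  toy <- toy_fixture()
  m <- fix_flux(toy$model, "BYP", 2, 2)
  expect_equal(m$reactions$lower_bound[m$reactions$id == "BYP"], 2)
  expect_equal(m$reactions$upper_bound[m$reactions$id == "BYP"], 2)
  # beyond the original bounds: overwritten, not intersected
  m2 <- fix_flux(toy$model, "BYP", -2000, 2000)
  expect_equal(m2$reactions$lower_bound[m2$reactions$id == "BYP"], -2000)
  expect_error(fix_flux(toy$model, "BYP", 1, 0), "lower > upper")
  expect_error(fix_flux(toy$model, "NOPE", 0, 0), "unknown reaction")
})

test_that("scenario application is idempotent", {
  toy <- toy_fixture()
  scen <- scenario_spec(medium = toy$medium,
                        supplements = toy$corrections$supplements,
                        isoenzyme_reassign = toy$corrections$isoenzyme_reassign,
                        irreversible = toy$corrections$irreversible)
  m1 <- apply_scenario(toy$model, scen, carbon_metabolite = "carb1_e")
  m2 <- apply_scenario(m1, scen, carbon_metabolite = "carb1_e")
  expect_equal(m2$reactions, m1$reactions)
  expect_equal(as.matrix(m2$S), as.matrix(m1$S))
})

test_that("the wild type grows on every configured carbon", {
  toy <- toy_fixture()
  for (i in seq_len(nrow(toy$carbons))) {
    m <- apply_scenario(toy$model, scenario_spec(medium = toy$medium),
                        carbon_metabolite = toy$carbons$metabolite[i])
    expect_gte(solve_fba(m)$objective_value, 0.001)
  }
})
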