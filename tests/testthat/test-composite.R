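# Rigid superposition, sequential assembly, clash census, distances.

test_that("superpose recovers planted rigid motions and stays proper", {
  set.seed(61)
  ref <- matrix(rnorm(50 * 3, sd = 8), 50, 3)
  # identity case
  tf0 <- superpose(ref, ref)
  expect_equal(tf0$rotation, diag(3), tolerance = 1e-9)
  expect_equal(tf0$translation, c(0, 0, 0), tolerance = 1e-9)
  expect_lt(tf0$rmsd, 1e-9)
  # construct-and-recover over random proper motions
  for (i in 1:25) {
    R <- random_rotation(); t <- rnorm(3, sd = 20)
    mobile <- sweep(ref %*% t(R), 2L, -t)  # rows rotated by R then shifted
    tf <- superpose(ref, mobile)
    expect_lt(tf$rmsd, 1e-6)
    expect_equal(det(tf$rotation), 1, tolerance = 1e-9)
    expect_equal(crossprod(tf$rotation), diag(3), tolerance = 1e-9)
    expect_lt(max(abs(transform_apply(tf, mobile) - ref)), 1e-6)
  }
})

test_that("mirror-image inputs still yield a proper rotation", {
  set.seed(62)
  ref <- matrix(rnorm(30 * 3, sd = 5), 30, 3)
  mirror <- ref %*% diag(c(-1, 1, 1))
  tf <- superpose(ref, mirror)
  expect_equal(det(tf$rotation), 1, tolerance = 1e-9)
  expect_gt(tf$rmsd, 0)
})

test_that("degenerate point sets are rejected", {
  line <- cbind(1:5, 2 * (1:5), 3 * (1:5))
  good <- matrix(rnorm(15), 5, 3)
  expect_error(superpose(good, line), class = "fs_degenerate")
  expect_error(superpose(line, good), class = "fs_degenerate")
  expect_error(superpose(good[1:2, ], good[1:2, ]), class = "fs_degenerate")
  expect_error(superpose(good, good[1:4, ]), class = "fs_bad_argument")
})

displaced_copy <- function(model, R, t) {
  xyz <- as.matrix(model$atoms[, c("x", "y", "z")])
  xyz <- sweep(xyz %*% R, 2L, -t)
  model$atoms$x <- xyz[, 1L]; model$atoms$y <- xyz[, 2L]
  model$atoms$z <- xyz[, 3L]
  model
}

test_that("align_via_chain fits on the anchor and moves the whole model", {
  ref <- toy_model(c(A = 6L, B = 5L), model_id = "ref")
  # self-alignment: identity
  self <- align_via_chain(ref, ref, chain_pairing("A"))
  expect_lt(self$transform$rmsd, 1e-9)
  # rigidly displaced copy comes back exactly
  set.seed(63)
  mob <- displaced_copy(ref, random_rotation(), rnorm(3, sd = 15))
  mob$model_id <- "mob"
  fit <- align_via_chain(ref, mob, chain_pairing("A"))
  expect_lt(fit$transform$rmsd, 1e-6)
  expect_lt(max(abs(as.matrix(fit$model$atoms[, c("x", "y", "z")]) -
                      as.matrix(ref$atoms[, c("x", "y", "z")]))), 1e-6)
  expect_equal(fit$transform$n_matched, 6L)  # alpha-carbons of chain A
  # backbone rule uses the N atoms too
  fit_bb <- align_via_chain(ref, mob, chain_pairing("A",
                                                    atom_rule = "backbone"))
  expect_equal(fit_bb$transform$n_matched, 12L)  # N + CA per residue
  # unknown anchor chain
  expect_error(align_via_chain(ref, mob, chain_pairing("Z")),
               class = "fs_unknown_chain")
})

test_that("two-step assembly equals the composed transform", {
  set.seed(64)
  base <- toy_model(c(A = 5L, B = 6L), model_id = "base")
  # component B shares chain B with base; component C shares chain C with B
  compB <- toy_model(c(B = 6L, C = 5L), offset = 14, model_id = "compB")
  compC <- toy_model(c(C = 5L, D = 7L), offset = 18, model_id = "compC")
  # displace both components arbitrarily
  compB <- displaced_copy(compB, random_rotation(), rnorm(3, sd = 12))
  compC <- displaced_copy(compC, random_rotation(), rnorm(3, sd = 12))

  comp <- assemble(base, list(
    list(mobile = compB, pairing = chain_pairing("B"), name = "B"),
    list(mobile = compC, reference = "B", pairing = chain_pairing("C"),
         name = "C")))
  expect_named(comp$components, c("B", "C"))

  # oracle: compose the two fits by hand
  fitB <- align_via_chain(base, compB, chain_pairing("B"))
  fitC <- align_via_chain(fitB$model, compC, chain_pairing("C"))
  via_composed <- transform_apply(
    transform_compose(comp$components[["C"]]$transform,
                      structure(list(rotation = diag(3),
                                     translation = c(0, 0, 0)),
                                class = "RigidTransform")),
    as.matrix(compC$atoms[, c("x", "y", "z")]))
  expect_lt(max(abs(as.matrix(comp$components[["C"]]$model$atoms[,
                      c("x", "y", "z")]) -
                      as.matrix(fitC$model$atoms[, c("x", "y", "z")]))),
            1e-6)
  expect_lt(max(abs(via_composed -
                      as.matrix(fitC$model$atoms[, c("x", "y", "z")]))),
            1e-6)

  # empty step list: composite is just the base
  expect_length(assemble(base)$components, 0L)
  # unplaced reference
  expect_error(assemble(base, list(list(mobile = compC, reference = "nope",
                                        pairing = chain_pairing("C")))),
               class = "fs_unknown_component")
})

test_that("chain-id collisions are disambiguated and recorded", {
  base <- toy_model(c(A = 4L, B = 4L), model_id = "base")
  mob <- toy_model(c(A = 4L, B = 4L), model_id = "mob")
  comp <- assemble(base, list(list(mobile = mob,
                                   pairing = chain_pairing("A"))))
  cm <- comp$components[[1L]]$chain_map
  expect_equal(unname(cm[["A"]]), "A_2")
  expect_equal(unname(cm[["B"]]), "B_2")
  flat <- flatten_composite(comp)
  expect_setequal(chain_ids(flat), c("A", "B", "A_2", "B_2"))
})

test_that("clash census equals the all-pairs oracle, including planted overlaps", {
  set.seed(65)
  for (rep_i in 1:4) {
    base <- toy_model(c(A = 5L, B = 4L + rep_i), model_id = "base")
    mob <- toy_model(c(A = 5L, C = 5L), offset = 9 + rep_i,
                     model_id = "mob")
    # plant overlapping atoms: shift a few C-chain residues on top of B
    shift <- mob$atoms$chain == "C" & mob$atoms$resnum <= rep_i
    mob$atoms$y[shift] <- mob$atoms$y[shift] - (9 + rep_i) + 10 +
      runif(sum(shift), -0.5, 0.5)
    comp <- assemble(base, list(list(mobile = mob,
                                     pairing = chain_pairing("A"),
                                     name = "mob")))
    for (rule in c("vdw", "fixed")) {
      got <- clash_census(comp, rule = rule)
      expect_identical(clash_pair_strings(got),
                       oracle_clashes(comp, rule = rule))
    }
  }
  # far-apart components: empty report
  base <- toy_model(c(A = 4L, B = 4L), model_id = "base")
  far <- toy_model(c(A = 4L, D = 4L), offset = 200, model_id = "far")
  comp <- assemble(base, list(list(mobile = far,
                                   pairing = chain_pairing("A"),
                                   name = "far")))
  expect_equal(nrow(clash_census(comp)$clashes), 0L)
})

test_that("measured distances follow the assembly transforms", {
  base <- toy_model(c(A = 4L, B = 4L), model_id = "base")
  comp0 <- assemble(base)
  selA <- list(component = "base", chain = "A", resnum = 1L, atom = "CA")
  expect_equal(measure_distance(comp0, selA, selA), 0)
  selB <- list(component = "base", chain = "B", resnum = 1L, atom = "CA")
  expect_equal(measure_distance(comp0, selA, selB), 10)  # offset construction

  # post-assembly: distance equals hand-composed transform arithmetic
  set.seed(66)
  mob <- toy_model(c(B = 4L, E = 3L), offset = 12, model_id = "mob")
  orig <- as.matrix(mob$atoms[, c("x", "y", "z")])
  mobd <- displaced_copy(mob, random_rotation(), rnorm(3, sd = 10))
  comp <- assemble(base, list(list(mobile = mobd,
                                   pairing = chain_pairing("B"),
                                   name = "mob")))
  tf <- comp$components[["mob"]]$transform
  sel_e <- list(component = "mob", chain = "E", resnum = 2L, atom = "CB")
  i <- which(mobd$atoms$chain == "E" & mobd$atoms$resnum == 2L &
               mobd$atoms$atom == "CB")
  want_xyz <- transform_apply(tf, as.matrix(mobd$atoms[i, c("x", "y", "z")]))
  a1 <- as.numeric(base$atoms[1L, c("x", "y", "z")])
  expect_equal(measure_distance(comp, sel_e,
                                list(component = "base", chain = "A",
                                     resnum = 1L, atom = "N")),
               sqrt(sum((want_xyz - as.numeric(
                 base$atoms[base$atoms$atom == "N" &
                              base$atoms$chain == "A" &
                              base$atoms$resnum == 1L,
                            c("x", "y", "z")]))^2)))
  # within-component distances are invariant under placement
  sel_e1 <- list(component = "mob", chain = "E", resnum = 1L, atom = "CA")
  sel_e3 <- list(component = "mob", chain = "E", resnum = 3L, atom = "CA")
  d_placed <- measure_distance(comp, sel_e1, sel_e3)
  i1 <- which(mob$atoms$chain == "E" & mob$atoms$resnum == 1L &
                mob$atoms$atom == "CA")
  i3 <- which(mob$atoms$chain == "E" & mob$atoms$resnum == 3L &
                mob$atoms$atom == "CA")
  expect_equal(d_placed, sqrt(sum((orig[i1, ] - orig[i3, ])^2)),
               tolerance = 1e-6)
  # ambiguous / unresolvable selectors
  expect_error(measure_distance(comp, selA,
                                list(component = "mob", chain = "E",
                                     resnum = 99L, atom = "CA")),
               class = "fs_bad_selector")
})
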