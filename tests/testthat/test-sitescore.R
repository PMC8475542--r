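# Three isolated single-atom residues 12 A apart; poses built to touch
# chosen residues give exact control over site membership.
three_residue_receptor <- function() {
  make_point_receptor(cbind(c(0, 12, 24), 0, 0))
}

pose_at <- function(x, id = "p", energy = -100)
  ligand_pose(id, data.frame(element = "C", x = x, y = 0, z = 0), energy)

test_that("the contact rule is inclusive at the cutoff: 3.4 A hits, 3.6 A misses", {
  rec <- three_residue_receptor()
  hit <- binding_site_residues(rec, pose_at(3.4))
  expect_equal(hit$keys, "A:1:")
  expect_equal(hit$n, 1L)
  miss <- binding_site_residues(rec, pose_at(3.6))
  expect_equal(miss$n, 0L)
  boundary <- binding_site_residues(rec, pose_at(3.5))
  expect_equal(boundary$n, 1L)  # "within" is inclusive
})

test_that("contact detection agrees with a brute-force all-pairs oracle on random fixtures", {
  for (seed in 1:25) {
    rec <- make_random_receptor(seed, n_res = 50L)
    pose <- make_random_pose(seed + 1000, n_atoms = 20L)
    expect_setequal(binding_site_residues(rec, pose)$keys,
                    brute_force_site(rec, pose))
  }
})

test_that("contact detection is invariant under joint rigid-body transforms", {
  rec <- make_random_receptor(7, n_res = 40L)
  pose <- make_random_pose(8, n_atoms = 15L)
  base <- binding_site_residues(rec, pose)$keys
  for (seed in 1:5) {
    rot <- random_rotation(seed)
    shift <- c(5, -3, 11) * seed
    moved <- binding_site_residues(transform_receptor(rec, rot, shift),
                                   transform_pose(pose, rot, shift))$keys
    expect_setequal(moved, base)
  }
})

test_that("the conservation score is the arithmetic mean of site residue values", {
  rec <- three_residue_receptor()
  prof <- conservation_profile(c("A:1:" = 0.8, "A:2:" = 0.6, "A:3:" = 1.0))
  pose <- ligand_pose("p", data.frame(element = "C", x = c(0, 12, 24),
                                      y = 0, z = 0), -100)
  site <- binding_site_residues(rec, pose, prof)
  expect_equal(site$n, 3L)
  expect_equal(conservation_score(site), 0.8)

  single <- binding_site_residues(rec, pose_at(0),
                                  conservation_profile(c("A:1:" = 0.42)))
  expect_equal(conservation_score(single), 0.42)

  set.seed(99)
  for (i in 1:10) {
    vals <- runif(7)
    rec7 <- make_point_receptor(cbind(seq(0, 72, by = 12), 0, 0))
    prof7 <- conservation_profile(setNames(vals, paste0("A:", 1:7, ":")))
    p7 <- ligand_pose("p", data.frame(element = "C", x = seq(0, 72, by = 12),
                                      y = 0, z = 0), -1)
    s7 <- binding_site_residues(rec7, p7, prof7)
    expect_equal(conservation_score(s7), sum(vals) / 7)
  }
})

test_that("empty or unvalued sites cannot be scored; missing values follow the policy", {
  rec <- three_residue_receptor()
  empty <- binding_site_residues(rec, pose_at(100))
  expect_error(conservation_score(empty), "empty")
  partial_prof <- conservation_profile(c("A:1:" = 0.5))
  pose <- ligand_pose("p", data.frame(element = "C", x = c(0, 12), y = 0,
                                      z = 0), -1)
  site <- binding_site_residues(rec, pose, partial_prof)
  expect_equal(site$missing, "A:2:")
  expect_message(v <- conservation_score(site, "omit"), "omitted")
  expect_equal(v, 0.5)
  expect_error(conservation_score(site, "strict"), "A:2:")
})

test_that("the combined score is the exact product, with guard rails", {
  expect_identical(condock_score(0.5, -100), -50)
  expect_identical(condock_score(0, -12345.6), 0)
  expect_identical(condock_score(1.0, -3421.7), -3421.7)
  expect_warning(condock_score(0.5, 10), "positive")
  expect_error(condock_score(0.5, Inf), "finite")
  expect_error(condock_score(1.2, -10), "\\[0, 1\\]")
})

test_that("score monotonicity: better conservation or better energy improves the score", {
  set.seed(17)
  for (i in 1:50) {
    cons <- runif(1, 0.05, 0.95)
    en <- -runif(1, 10, 2000)
    expect_lt(condock_score(cons + 0.04, en), condock_score(cons, en))
    expect_lt(condock_score(cons, en - 50), condock_score(cons, en))
  }
})

test_that("poses rank by ascending combined score with the documented example", {
  rec <- three_residue_receptor()
  prof <- conservation_profile(c("A:1:" = 0.9, "A:2:" = 0.5, "A:3:" = 0.9))
  poses <- list(pose_at(0, "p1", -100),    # cons 0.9 -> -90
                pose_at(12, "p2", -150),   # cons 0.5 -> -75
                pose_at(24, "p3", -50))    # cons 0.9 -> -45
  rk <- rank_poses(rec, poses, prof)
  expect_equal(rk$predictions$pose_id, c("p1", "p2", "p3"))
  expect_equal(rk$predictions$condock_score, c(-90, -75, -45))
  expect_equal(rk$predictions$rank, 1:3)
})

test_that("exact combined-score ties break by energy, then pose id", {
  rec <- three_residue_receptor()
  prof <- conservation_profile(c("A:1:" = 0.8, "A:2:" = 8 / 9))
  poses <- list(pose_at(0, "pa", -100),        # 0.8    * -100 = -80
                pose_at(12, "pb", -90))        # 8/9    * -90  = -80
  rk <- rank_poses(rec, poses, prof)
  expect_equal(rk$predictions$condock_score, c(-80, -80))
  expect_equal(rk$predictions$pose_id[1], "pa")  # more negative energy first
  # pure id tie-break: same residue, same energy
  poses2 <- list(pose_at(0, "z", -100), pose_at(0, "a", -100))
  rk2 <- rank_poses(rec, poses2, prof)
  expect_equal(rk2$predictions$pose_id, c("a", "z"))
})

test_that("ranking is a permutation: empty-site poses are appended unranked with a reason", {
  rec <- three_residue_receptor()
  prof <- conservation_profile(c("A:1:" = 0.9))
  poses <- list(pose_at(0, "good", -100), pose_at(100, "lost", -500))
  rk <- rank_poses(rec, poses, prof)
  expect_equal(nrow(rk$predictions) + nrow(rk$unranked), 2L)
  expect_equal(rk$predictions$rank, 1L)
  expect_equal(rk$unranked$pose_id, "lost")
  expect_equal(rk$unranked$reason, "empty_site")
  expect_error(rank_poses(rec, list(pose_at(100, "lost", -1)), prof),
               "zero scoreable")
})

test_that("a constant conservation surface reduces the combined ranking to the energy ranking", {
  sc <- make_scenario(scenario_spec(seed = 23))
  res <- receptor_residues(sc$receptor)
  flat <- conservation_profile(setNames(rep(0.5, nrow(res)), res$key))
  rk <- rank_poses(sc$receptor, sc$poses, flat)
  en <- vapply(rk$poses[rk$predictions$pose_id], `[[`, 0, "energy_score")
  expect_equal(rk$predictions$pose_id,
               rk$predictions$pose_id[order(en)])
  expect_equal(rk$predictions$condock_score, unname(0.5 * sort(en)))
})

test_that("the rescue scenario reproduces conservation overriding the energy rank", {
  sc <- make_scenario(scenario_spec(seed = 77, true_energy_percentile = 0.7))
  prof <- scenario_profile(sc)
  rk <- rank_poses(sc$receptor, sc$poses, prof)
  ids <- vapply(sc$poses, `[[`, "", "pose_id")
  en <- vapply(sc$poses, `[[`, 0, "energy_score")
  energy_rank_of_truth <- which(ids[order(en)] == sc$truth)
  expect_gt(energy_rank_of_truth, 1L)          # docking alone gets it wrong
  expect_equal(rk$predictions$pose_id[1], sc$truth)  # the combined score recovers it
  expect_equal(predicted_site(rk)$keys,
               rk$sites[[sc$truth]]$keys)
})

test_that("ranked output writes a well-formed TSV", {
  sc <- make_scenario(scenario_spec(seed = 3, n_decoys = 3))
  rk <- rank_poses(sc$receptor, sc$poses, scenario_profile(sc))
  out <- withr::local_tempfile(fileext = ".tsv")
  write_ranked_tsv(rk, out, meta = "# test")
  tab <- read.table(out, header = TRUE, sep = "\t", comment.char = "#")
  expect_equal(nrow(tab), nrow(rk$predictions))
  expect_equal(tab$rank, seq_len(nrow(tab)))
  expect_true(all(diff(tab$condock_score) >= 0))
})
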