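chain_coords <- function(n, spacing = 3.8) {
  data.frame(residue_id = 1:n, x = (0:(n - 1)) * spacing, y = 0, z = 0)
}

test_that("JRP edge weights are counts over distances, zero counts dropped", {
  coords <- data.frame(residue_id = 1:3, x = c(0, 10, 20), y = 0, z = 0)
  counts <- data.frame(res_a = c(1, 1, 2), res_b = c(2, 3, 3),
                       count = c(100, 0, 100))
  net <- build_jrp_network(counts, coords)
  el <- edge_list(net)
  expect_equal(nrow(el), 2)  # the zero-count pair has no edge
  w12 <- el$weight[el$res_a == "1" & el$res_b == "2"]
  w23 <- el$weight[el$res_a == "2" & el$res_b == "3"]
  expect_equal(w12, 10)          # 100 / 10 A
  expect_equal(w23, 10)
  # equal counts at 5 A and 10 A give weights 2:1
  coords2 <- data.frame(residue_id = 1:3, x = c(0, 5, 15), y = 0, z = 0)
  el2 <- edge_list(build_jrp_network(
    data.frame(res_a = c(1, 2), res_b = c(2, 3), count = c(50, 50)),
    coords2))
  expect_equal(el2$weight[1] / el2$weight[2], 2)
  expect_equal(el2$path_length, 1 / el2$weight)
})

test_that("JRP network rejects missing coordinates and coincident residues", {
  coords <- data.frame(residue_id = 1:2, x = c(0, 0), y = 0, z = 0)
  counts <- data.frame(res_a = 1, res_b = 2, count = 5)
  expect_error(build_jrp_network(counts, coords), "zero")
  expect_error(
    build_jrp_network(data.frame(res_a = 1, res_b = 9, count = 5),
                      chain_coords(3)),
    "9")
})

test_that("unweighted 7 A network of a straight chain is a path graph", {
  net <- build_unweighted_network(chain_coords(8), cutoff = 7)
  el <- edge_list(net)
  expect_equal(nrow(el), 7)
  expect_true(all(el$weight == 1))
  expect_true(all(abs(as.integer(el$res_a) - as.integer(el$res_b)) == 1))
  # cutoff beyond the chain length gives the complete graph
  el_all <- edge_list(build_unweighted_network(chain_coords(5),
                                               cutoff = 1000))
  expect_equal(nrow(el_all), choose(5, 2))
  # two residues exactly at the cutoff are connected (<= convention)
  co <- data.frame(residue_id = 1:2, x = c(0, 7), y = 0, z = 0)
  expect_equal(nrow(edge_list(build_unweighted_network(co, 7))), 1)
})

test_that("contact network passes counts through and derives them from atoms", {
  coords <- chain_coords(3, spacing = 10)
  contacts <- data.frame(res_a = c(1, 2), res_b = c(3, 3),
                         count = c(4, 0))
  el <- edge_list(build_contact_network(coords, contacts = contacts))
  expect_equal(nrow(el), 1)
  expect_equal(el$weight, 4)
  # toy two-residue structure: exactly 3 heavy-atom pairs within 4.5 A
  # (residue 1: N at 0 and CA at 1.5; residue 2: CA at 4.0 and O at 9)
  pdb <- withr::local_tempfile(fileext = ".pdb")
  writeLines(c(
    "ATOM      1  N   ALA A   1       0.000   0.000   0.000  1.00  0.00           N",
    "ATOM      2  CA  ALA A   1       1.500   0.000   0.000  1.00  0.00           C",
    "ATOM      3  H   ALA A   1       4.100   0.000   0.000  1.00  0.00           H",
    "ATOM      4  CA  ALA A   2       4.000   0.000   0.000  1.00  0.00           C",
    "ATOM      5  CB  ALA A   2       5.900   0.000   0.000  1.00  0.00           C",
    "ATOM      6  O   ALA A   2       9.000   0.000   0.000  1.00  0.00           O",
    "END"), pdb)
  # brute force: |0-4|=4 yes, |1.5-4|=2.5 yes, |1.5-5.9|=4.4 yes,
  # |0-5.9|, |*-9| no; hydrogen excluded
  cc <- contact_counts_from_pdb(pdb)
  expect_equal(cc$count, 3)
  co2 <- data.frame(residue_id = 1:2, x = c(0.75, 6.3), y = 0, z = 0)
  el2 <- edge_list(build_contact_network(co2, pdb = pdb))
  expect_equal(el2$weight, 3)
  # all atoms farther than 4.5 A: no edge
  pdb2 <- withr::local_tempfile(fileext = ".pdb")
  writeLines(c(
    "ATOM      1  CA  ALA A   1       0.000   0.000   0.000  1.00  0.00           C",
    "ATOM      2  CA  ALA A   2       8.000   0.000   0.000  1.00  0.00           C",
    "END"), pdb2)
  expect_equal(nrow(contact_counts_from_pdb(pdb2)), 0)
})

test_that("closeness reproduces closed forms on path and complete graphs", {
  path3 <- build_contact_network(
    chain_coords(3), contacts = data.frame(res_a = c(1, 2),
                                           res_b = c(2, 3), count = 1))
  cl <- closeness_centrality(path3)
  expect_equal(unname(cl[c("1", "2", "3")]), c(2 / 3, 1, 2 / 3))
  full <- build_unweighted_network(chain_coords(6), cutoff = 1000)
  expect_equal(as.numeric(closeness_centrality(full)), rep(1, 6))
})

test_that("betweenness reproduces path and star closed forms", {
  path3 <- build_contact_network(
    chain_coords(3), contacts = data.frame(res_a = c(1, 2),
                                           res_b = c(2, 3), count = 1))
  b <- betweenness_centrality(path3)
  expect_equal(unname(b[c("1", "2", "3")]), c(0, 1, 0))
  for (k in c(4, 7)) {
    coords <- data.frame(residue_id = 1:(k + 1),
                         x = c(0, 100 * cos(2 * pi * (1:k) / k)),
                         y = c(0, 100 * sin(2 * pi * (1:k) / k)), z = 0)
    star <- build_contact_network(
      coords, contacts = data.frame(res_a = 1, res_b = 2:(k + 1),
                                    count = 1))
    bs <- betweenness_centrality(star)
    expect_equal(unname(bs["1"]), k * (k - 1) / 2)
    expect_equal(unname(bs[-1]), rep(0, k))
  }
})

test_that("centralities match brute-force oracles on random weighted graphs", {
  for (seed in 1:20) {
    rw <- random_weighted_net(seed)
    expect_equal(unname(betweenness_centrality(rw$net)),
                 oracle_betweenness(rw$L))
    expect_equal(as.numeric(closeness_centrality(rw$net)),
                 oracle_closeness(rw$L), tolerance = 1e-9)
  }
})

test_that("disconnected components are handled and flagged", {
  coords <- chain_coords(5)
  net <- build_contact_network(
    coords, contacts = data.frame(res_a = c(1, 4), res_b = c(2, 5),
                                  count = c(2, 2)))
  cl <- closeness_centrality(net)
  expect_true(all(attr(cl, "disconnected")))
  # each two-node component: (r-1)/sum(sd) with edge length 1/2
  expect_equal(unname(cl["1"]), 1 / 0.5)
  expect_equal(unname(cl["3"]), 0)  # isolated node
})

test_that("standardization has exact moments and rejects degenerate input", {
  z <- standardize(c(1, 2, 3))
  expect_equal(z, c(-1, 0, 1) * sqrt(3 / 2), tolerance = 1e-12)
  expect_error(standardize(rep(5, 4)), "degenerate")
  set.seed(30)
  v <- rnorm(50)
  zs <- standardize(v)
  expect_lt(abs(mean(zs)), 1e-12)
  expect_equal(sqrt(mean((zs - mean(zs))^2)), 1, tolerance = 1e-12)
})

test_that("uniform weight rescaling leaves centralities and z-scores unchanged", {
  counts <- expand.grid(res_a = 1:6, res_b = 1:6)
  counts <- counts[counts$res_a < counts$res_b, ]
  set.seed(17)
  counts$count <- sample(0:30, nrow(counts), replace = TRUE)
  coords <- data.frame(residue_id = 1:6, x = runif(6, 0, 30),
                       y = runif(6, 0, 30), z = runif(6, 0, 30))
  net1 <- build_jrp_network(counts, coords)
  counts2 <- counts
  counts2$count <- counts2$count * 7
  net2 <- build_jrp_network(counts2, coords)
  t1 <- centrality_table(net1)
  t2 <- centrality_table(net2)
  expect_equal(t1$B, t2$B)
  expect_equal(t2$C, 7 * t1$C)      # closeness scales, rankings don't
  expect_equal(t1$z_B, t2$z_B, tolerance = 1e-9)
  expect_equal(t1$z_C, t2$z_C, tolerance = 1e-9)
})

test_that("closeness of the straight-chain cutoff network peaks centrally", {
  net <- build_unweighted_network(chain_coords(9), cutoff = 7)
  cl <- closeness_centrality(net)
  expect_identical(names(which.max(cl)), "5")
})

test_that("significant residues are filtered and annotated with neighbors", {
  path3 <- build_contact_network(
    chain_coords(3), contacts = data.frame(res_a = c(1, 2),
                                           res_b = c(2, 3), count = 1))
  tab <- data.frame(residue_id = as.character(1:3),
                    B = c(0, 1, 0), C = c(2 / 3, 1, 2 / 3),
                    z_B = c(-0.5, 2.5, -0.5), z_C = c(-0.7, 1.6, -0.7))
  sig <- significant_residues(tab, path3)
  expect_equal(sig$residue_id, "2")
  expect_equal(sig$criterion, "B+C")
  ann <- data.frame(residue_id = c(1, 3), label = c("C1", "site"))
  sig2 <- significant_residues(tab, path3, annotations = ann)
  expect_match(sig2$significant_neighbors, "1 \\(C1\\)")
  expect_match(sig2$significant_neighbors, "3 \\(site\\)")
  # nothing significant is an empty result, not an error
  none <- significant_residues(tab, path3, z_b_min = 10, z_c_min = 10)
  expect_equal(nrow(none), 0)
  # simple z_B threshold filter
  tabz <- data.frame(residue_id = c("a", "b", "c"), B = 1:3, C = 1:3,
                     z_B = c(2.5, 1.0, 0.5), z_C = c(0, 0, 0))
  sigz <- significant_residues(tabz, path3)
  expect_equal(sigz$residue_id, "a")
})

test_that("weight-to-length rules behave and alternatives are available", {
  expect_equal(path_length_from_weight(c(2, 4)), c(0.5, 0.25))
  nl <- path_length_from_weight(c(2, 4), rule = "neglog")
  expect_equal(nl, c(log(2), 0))
  expect_error(path_length_from_weight(c(1, 0)), "> 0")
})
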