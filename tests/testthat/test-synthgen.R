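test_that("generators are pure functions of the configuration", {
  cfg <- synth_config(seed = 12, n_nodes = 100)
  a <- synth_network(cfg); b <- synth_network(cfg)
  expect_identical(network_edges(a$network), network_edges(b$network))
  expect_identical(as.data.frame(a$pool), as.data.frame(b$pool))
  ann_a <- synth_annotations(a$network, cfg)
  ann_b <- synth_annotations(b$network, cfg)
  expect_identical(ann_a, ann_b)
  ex_a <- synth_expression(network_nodes(a$network), cfg)
  ex_b <- synth_expression(network_nodes(a$network), cfg)
  expect_identical(ex_a$matrix, ex_b$matrix)
  c2 <- synth_network(synth_config(seed = 13, n_nodes = 100))
  expect_false(identical(network_edges(a$network), network_edges(c2$network)))
})

test_that("preferential attachment yields the closed-form edge count", {
  cfg <- synth_config(seed = 1, n_nodes = 100, n_edges_per_node = 3)
  net <- synth_network(cfg)$network
  expect_equal(nrow(network_edges(net)), 3 + 97 * 3)  # m-cycle + (n-m)*m
  expect_length(network_nodes(net), 100)
  expect_true(igraph::is_connected(as_igraph(net)))
  expect_true(all(network_edges(net)$confidence >= 0.5 &
                  network_edges(net)$confidence <= 1))
})

test_that("degree distribution is heavy-tailed with a plausible exponent", {
  gammas <- vapply(1:3, function(s) {
    net <- synth_network(synth_config(seed = s, n_nodes = 1200))$network
    fit_power_law(table(igraph::degree(as_igraph(net))))
  }, numeric(1))
  expect_true(all(gammas > 1.0 & gammas < 3.5))
})

test_that("annotations always include the planted structures", {
  for (s in c(3, 8)) {
    cfg <- synth_config(seed = s)
    nets <- synth_network(cfg)
    ann <- synth_annotations(nets$network, cfg)
    g <- as_igraph(nets$network)
    deg <- igraph::degree(g)
    nbr <- function(v) igraph::V(g)$name[igraph::neighbors(g, v)]
    # specific neighbour: low degree, every neighbour a seed, not a seed
    expect_lte(deg[ann$planted$specific], 5)
    expect_true(all(nbr(ann$planted$specific) %in% ann$seed_genes))
    expect_false(ann$planted$specific %in% ann$seed_genes)
    # promiscuous hub: top degree, seed connectivity pinned near the
    # realized degree-weighted trend of the other candidates
    expect_equal(unname(deg[ann$planted$hub]), max(deg))
    k_seed <- sum(nbr(ann$planted$hub) %in% ann$seed_genes)
    others <- setdiff(
      igraph::V(g)$name[vapply(igraph::V(g)$name, function(v)
        any(nbr(v) %in% ann$seed_genes), logical(1))],
      c(ann$seed_genes, ann$planted$hub, ann$planted$specific,
        ann$planted$expression_genes))
    emt_o <- vapply(others, function(v) sum(nbr(v) %in% ann$seed_genes),
                    numeric(1))
    # post-hoc trend includes the hub's own seed neighbours, so allow a
    # modest construction-vs-measurement gap
    q_hat <- sum(emt_o) / sum(deg[others])
    expect_lt(abs(k_seed / deg[ann$planted$hub] - q_hat), 0.15)
    expect_gt(k_seed / deg[ann$planted$hub], cfg$seed_gene_fraction / 2)
    # expression genes are built like the specific neighbour
    for (gene in ann$planted$expression_genes) {
      expect_true(all(nbr(gene) %in% ann$seed_genes))
      expect_false(gene %in% ann$seed_genes)
    }
    # no cancer annotation on planted survivors
    cancer <- ann$doid_map$gene[grepl("cancer|glioma|tumor",
                                      paste(ann$doid_map$term_name,
                                            ann$doid_map$slim))]
    expect_false(any(c(ann$planted$specific, ann$planted$hub,
                       ann$planted$expression_genes) %in% cancer))
  }
  # degenerate fraction: no free seeds, only the forced neighbourhoods of
  # the planted genes plus the hub's trend-pinning picks remain
  cfg0 <- synth_config(seed = 3, seed_gene_fraction = 0)
  nets0 <- synth_network(cfg0)
  ann0 <- synth_annotations(nets0$network, cfg0)
  g0 <- as_igraph(nets0$network)
  nbr0 <- function(v) igraph::V(g0)$name[igraph::neighbors(g0, v)]
  forced <- unique(unlist(lapply(c(ann0$planted$specific,
                                   ann0$planted$expression_genes), nbr0)))
  expect_true(all(ann0$seed_genes %in% union(forced, nbr0(ann0$planted$hub))))
  expect_true(all(forced %in% ann0$seed_genes))
})

test_that("synthetic expression has log-normal support and honest nulls", {
  cfg <- synth_config(seed = 22, n_planted = 0)
  study <- synth_expression(sprintf("G%04d", 1:50), cfg,
                            planted = data.frame(gene = character(0),
                                                 transition = character(0),
                                                 log2fc = numeric(0)))
  expect_true(all(study$matrix >= 0))
  study <- suppressMessages(build_cohorts(study))
  co <- study$cohorts$SYN1
  # null genes: empirical |log2fc| stays small at n = 30
  l2 <- vapply(rownames(study$matrix), function(g) {
    fold_change(study$matrix[g, co$primary], study$matrix[g, co$metastatic])$log2fc
  }, numeric(1))
  expect_gte(mean(abs(l2) < 0.5), 0.6)
  expect_lt(abs(mean(l2)), 0.2)
})

test_that("planted fold changes surface in the cohort means", {
  cfg <- synth_config(seed = 30)
  planted <- data.frame(gene = c("G0001", "G0002"),
                        transition = c("primary_metastatic", "normal_primary"),
                        log2fc = c(3, 2), stringsAsFactors = FALSE)
  study <- synth_expression(sprintf("G%04d", 1:20), cfg, planted = planted)
  study <- suppressMessages(build_cohorts(study))
  co <- study$cohorts$SYN1
  l2_pm <- fold_change(study$matrix["G0001", co$primary],
                       study$matrix["G0001", co$metastatic])$log2fc
  l2_np <- fold_change(study$matrix["G0002", co$normal],
                       study$matrix["G0002", co$primary])$log2fc
  expect_gt(l2_pm, 2)
  expect_gt(l2_np, 1)
})

test_that("samples flagged with missing TNM codes never enter cohorts", {
  cfg <- synth_config(seed = 40, missing_tnm_fraction = 0.2)
  study <- synth_expression(sprintf("G%04d", 1:10), cfg)
  study <- suppressMessages(build_cohorts(study))
  miss <- study$metadata$sample_id[grepl("MISS", study$metadata$sample_id)]
  expect_gt(length(miss), 0)
  expect_false(any(miss %in% unlist(study$cohorts)))
})

test_that("written fixtures round-trip through the package readers", {
  outdir <- withr::local_tempdir()
  cfg <- synth_config(seed = 18, n_nodes = 60)
  paths <- write_synth_fixtures(cfg, outdir)
  expect_true(all(file.exists(paths)))
  net <- read_network_tsv(paths[["net"]])
  ds <- suppressMessages(synth_dataset(cfg))
  expect_equal(network_edges(net), network_edges(ds$network))
  pool <- read_edge_table(paths[["pool"]], "generic")
  expect_equal(nrow(pool), nrow(ds$pool))
  expect_identical(read_seed_list(paths[["seeds"]]), ds$seed_genes)
  doid <- read_doid_map(paths[["doid"]])
  expect_equal(doid$gene, ds$doid_map$gene)
  m <- read_expression_matrix(paths[["fpkm"]])
  expect_equal(dim(m), dim(ds$study$matrix))
  expect_equal(m[3, 5], ds$study$matrix[3, 5], tolerance = 1e-6)
  md <- read_sample_metadata(paths[["meta"]])
  expect_identical(md$sample_id, ds$study$metadata$sample_id)
})
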