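#' Configuration for the synthetic-data generators
#'
#' Collects every knob of the seeded generators that emulate the pipeline's
#' inputs: a sparse heavy-tailed interaction network with an expansion pool,
#' a seed (EMT) gene list with Disease Ontology annotations, and log-normal
#' FPKM cohorts with planted fold changes.
#'
#' @param n_nodes network size (>= 20).
#' @param n_edges_per_node preferential-attachment edges per added node.
#' @param seed master RNG seed; every generator output is a pure function of
#'   the configuration.
#' @param seed_gene_fraction fraction of nodes tagged as seed (EMT) genes.
#' @param cancer_doid_fraction fraction of candidate genes given a
#'   cancer-related DO term (exercises the annotation filter).
#' @param n_planted number of genes planted with a differential-expression
#'   effect; they are constructed as low-degree candidates with excess seed
#'   connectivity so they survive both prioritization filters.
#' @param planted_log2fc log2 fold change planted in the later cohort of
#'   `planted_transition`.
#' @param planted_transition `"primary_metastatic"` or `"normal_primary"`.
#' @param cohort_sizes named counts (normal / primary / metastatic), each
#'   >= 2.
#' @param fpkm_logmean,fpkm_logsd log-normal FPKM parameters (natural-log
#'   scale); per-gene baselines are drawn around `fpkm_logmean`.
#' @param cancer_types character vector of synthetic cancer-type codes.
#' @param missing_tnm_fraction fraction of extra tumour samples emitted with
#'   a TX/NX/MX code to exercise the exclusion rule.
#' @param pool_nodes,pool_edges_per_node size of the disjoint expansion
#'   pool.
#' @return A `synth_config` list.
#' @export
synth_config <- function(n_nodes = 200, n_edges_per_node = 3, seed = 1L,
                         seed_gene_fraction = 0.25,
                         cancer_doid_fraction = 0.2,
                         n_planted = 10, planted_log2fc = 3,
                         planted_transition = "primary_metastatic",
                         cohort_sizes = c(normal = 30, primary = 30,
                                          metastatic = 30),
                         fpkm_logmean = 3, fpkm_logsd = 1,
                         cancer_types = "SYN1",
                         missing_tnm_fraction = 0.05,
                         pool_nodes = 25, pool_edges_per_node = 3) {
  stopifnot(n_nodes >= 20, n_edges_per_node >= 1,
            seed_gene_fraction >= 0, seed_gene_fraction <= 1,
            cancer_doid_fraction >= 0, cancer_doid_fraction <= 1,
            missing_tnm_fraction >= 0, missing_tnm_fraction <= 1,
            all(cohort_sizes >= 2),
            all(c("normal", "primary", "metastatic") %in% names(cohort_sizes)),
            planted_transition %in% c("primary_metastatic", "normal_primary"))
  structure(list(n_nodes = n_nodes, n_edges_per_node = n_edges_per_node,
                 seed = as.integer(seed),
                 seed_gene_fraction = seed_gene_fraction,
                 cancer_doid_fraction = cancer_doid_fraction,
                 n_planted = n_planted, planted_log2fc = planted_log2fc,
                 planted_transition = planted_transition,
                 cohort_sizes = cohort_sizes,
                 fpkm_logmean = fpkm_logmean, fpkm_logsd = fpkm_logsd,
                 cancer_types = cancer_types,
                 missing_tnm_fraction = missing_tnm_fraction,
                 pool_nodes = pool_nodes,
                 pool_edges_per_node = pool_edges_per_node),
            class = "synth_config")
}

#' Generate a synthetic interaction network and expansion pool
#'
#' Grows a preferential-attachment graph: the first `m = n_edges_per_node`
#' nodes form a cycle (an edge pair for m = 2, a single edge for m = 1) and
#' each subsequent node attaches to `m` distinct existing nodes sampled
#' proportionally to their degree, yielding the heavy-tailed degree
#' distributions typical of interaction networks. For m >= 3 the edge count
#' is exactly `m + (n_nodes - m) * m`. Edge confidences are drawn uniformly
#' on \[0.5, 1\] (rounded to 4 decimals so files round-trip exactly).
#'
#' A disjoint pool of `pool_nodes` external nodes, each linked to
#' `pool_edges_per_node` network nodes, is returned alongside for expansion
#' experiments.
#'
#' @param cfg a [synth_config()].
#' @return List with `network` (a [ppi_network()]) and `pool` (an
#'   [edge_table()]).
#' @export
synth_network <- function(cfg) {
  stopifnot(inherits(cfg, "synth_config"))
  withr::with_seed(derive_seed(cfg$seed, 1), {
    n <- cfg$n_nodes; m <- cfg$n_edges_per_node
    syms <- sprintf("G%04d", seq_len(n))
    deg <- numeric(n)
    if (m >= 3) {
      from <- seq_len(m); to <- c(seq_len(m)[-1], 1L)
      first_new <- m + 1L
    } else if (m == 2) {
      from <- 1L; to <- 2L; first_new <- 3L
    } else {
      from <- 1L; to <- 2L; first_new <- 3L
    }
    ea <- from; eb <- to
    deg[from] <- deg[from] + 1; deg[to] <- deg[to] + 1
    for (v in seq(first_new, n)) {
      existing <- seq_len(v - 1L)
      k <- min(m, length(existing))
      targets <- sample(existing, k, prob = deg[existing])
      ea <- c(ea, rep(v, k)); eb <- c(eb, targets)
      deg[v] <- deg[v] + k; deg[targets] <- deg[targets] + 1
    }
    conf <- round(stats::runif(length(ea), 0.5, 1), 4)
    net <- ppi_network(data.frame(node_a = syms[ea], node_b = syms[eb],
                                  score = conf, stringsAsFactors = FALSE))
    pool_syms <- sprintf("P%03d", seq_len(cfg$pool_nodes))
    pa <- character(0); pb <- character(0)
    for (p in pool_syms) {
      tgt <- sample(syms, cfg$pool_edges_per_node)
      pa <- c(pa, rep(p, length(tgt))); pb <- c(pb, tgt)
    }
    pool <- edge_table(data.frame(
      node_a = pa, node_b = pb,
      score = round(stats::runif(length(pa), 0.5, 1), 4),
      stringsAsFactors = FALSE))
    list(network = net, pool = pool)
  })
}

#' Generate seed-gene annotations and a Disease Ontology map
#'
#' Tags `seed_gene_fraction` of the nodes as seed (EMT) genes and builds a
#' gene-to-DO-term map in which `cancer_doid_fraction` of the candidate
#' genes carry a cancer-related term. Three structures are always planted:
#' \itemize{
#'   \item a *promiscuous hub*: the highest-degree non-seed node, whose
#'     seed connectivity is pinned to the realized degree-weighted
#'     seed-connectivity trend of the other prospective candidates, i.e. it
#'     is consistent with the degree-explained trend and should be
#'     eliminated by the connectivity filter;
#'   \item a *specific neighbour*: a low-degree node all of whose
#'     neighbours are seeds, an outlier above the trend that should survive;
#'   \item `n_planted` *expression genes* constructed like the specific
#'     neighbour (and kept free of cancer DO terms) so they reach the
#'     differential-expression stage by construction.
#' }
#'
#' @param net the network from [synth_network()].
#' @param cfg the same [synth_config()].
#' @return List with `seed_genes` (character), `doid_map` (data frame:
#'   `gene`, `doid`, `term_name`, `slim`) and `planted` (list with `hub`,
#'   `specific`, `expression_genes`).
#' @export
synth_annotations <- function(net, cfg) {
  stopifnot(inherits(net, "ppi_network"), inherits(cfg, "synth_config"))
  withr::with_seed(derive_seed(cfg$seed, 2), {
    g <- net$graph
    syms <- igraph::V(g)$name
    deg <- igraph::degree(g)
    nbrs <- function(v) igraph::V(g)$name[igraph::neighbors(g, v)]
    hub <- syms[order(-deg, syms)][1]
    hub_nbrs <- nbrs(hub)
    q <- cfg$seed_gene_fraction
    # protected low-degree nodes: pairwise non-adjacent, away from the hub
    eligible <- syms[deg >= 2 & deg <= 5 & syms != hub & !(syms %in% hub_nbrs)]
    eligible <- sample(eligible)
    protected <- character(0)
    blocked <- character(0)
    # two passes: prefer nodes whose neighbourhood avoids the hub's (so the
    # hub's seed connectivity can be pinned exactly), then relax on small
    # networks where such nodes are scarce
    for (strict in c(TRUE, FALSE)) {
      for (v in eligible) {
        if (length(protected) >= cfg$n_planted + 1) break
        if (v %in% blocked) next
        vn <- nbrs(v)
        if (strict && any(vn %in% hub_nbrs)) next
        protected <- c(protected, v)
        blocked <- union(blocked, c(v, vn))
      }
    }
    if (length(protected) < cfg$n_planted + 1) {
      stop("network too small to place ", cfg$n_planted + 1,
           " planted low-degree genes; increase n_nodes")
    }
    specific <- protected[1]
    expr_genes <- protected[-1]
    forced <- unique(unlist(lapply(protected, nbrs)))
    quota <- round(q * length(syms))
    rest <- setdiff(syms, c(forced, protected, hub, hub_nbrs))
    extra <- if (quota > length(forced) && length(rest) > 0) {
      sample(rest, min(quota - length(forced), length(rest)))
    } else character(0)
    seeds0 <- unique(c(forced, extra))
    # pin the hub to the realized degree-weighted seed-connectivity trend of
    # the prospective candidates (not the nominal fraction: forced seeds
    # cluster on high-degree nodes and pull the trend slightly above it), so
    # the hub is trend-consistent by construction
    adj <- igraph::as_adjacency_matrix(g, sparse = TRUE)
    emt_cnt <- stats::setNames(as.numeric(adj %*% as.numeric(syms %in% seeds0)),
                               syms)
    pool <- setdiff(syms[emt_cnt > 0], c(seeds0, protected, hub))
    q_hat <- if (length(pool) > 0) sum(emt_cnt[pool]) / sum(deg[pool]) else q
    k_target <- min(round(q_hat * deg[hub]), length(hub_nbrs))
    k_have <- sum(hub_nbrs %in% seeds0)
    hub_seed <- if (k_target > k_have) {
      sample(setdiff(hub_nbrs, seeds0), k_target - k_have)
    } else character(0)
    seeds <- sort(unique(c(seeds0, hub_seed)))
    # candidates for annotation purposes: neighbours of seeds, minus seeds
    cand_idx <- unique(unlist(igraph::ego(g, order = 1, nodes = seeds,
                                          mindist = 1)))
    candidates <- sort(setdiff(syms[cand_idx], seeds))
    cancer_terms <- c("malignant glioma", "breast cancer",
                      "tumor of unknown origin", "stomach cancer")
    benign_terms <- c("diabetes mellitus", "rheumatoid arthritis",
                      "essential hypertension", "asthma")
    open <- setdiff(candidates, c(protected, hub))
    n_cancer <- round(cfg$cancer_doid_fraction * length(candidates))
    cancer_genes <- if (n_cancer > 0 && length(open) > 0) {
      sample(open, min(n_cancer, length(open)))
    } else character(0)
    benign_pool <- setdiff(candidates, cancer_genes)
    benign_genes <- benign_pool[stats::runif(length(benign_pool)) < 0.5]
    doid_map <- rbind(
      if (length(cancer_genes) > 0) data.frame(
        gene = cancer_genes,
        doid = sprintf("DOID:%04d", seq_along(cancer_genes)),
        term_name = sample(cancer_terms, length(cancer_genes), replace = TRUE),
        slim = "cancer_DO_slim", stringsAsFactors = FALSE),
      if (length(benign_genes) > 0) data.frame(
        gene = benign_genes,
        doid = sprintf("DOID:9%03d", seq_along(benign_genes)),
        term_name = sample(benign_terms, length(benign_genes), replace = TRUE),
        slim = "", stringsAsFactors = FALSE))
    if (is.null(doid_map)) {
      doid_map <- data.frame(gene = character(0), doid = character(0),
                             term_name = character(0), slim = character(0),
                             stringsAsFactors = FALSE)
    }
    doid_map <- doid_map[order(doid_map$gene), , drop = FALSE]
    rownames(doid_map) <- NULL
    list(seed_genes = seeds, doid_map = doid_map,
         planted = list(hub = hub, specific = specific,
                        expression_genes = sort(expr_genes)))
  })
}

#' Generate a synthetic FPKM expression study
#'
#' Draws log-normal FPKM values for every gene and sample; each gene gets
#' its own baseline (meanlog drawn around `fpkm_logmean`) shared across
#' cohorts, so under the null the expected fold change is 1. Planted genes
#' have every sample of the later cohorts multiplied by `2^log2fc`: the
#' metastatic cohort for a primary-to-metastatic effect, both tumour cohorts
#' for a normal-to-primary effect (the effect persists through later disease
#' stages, so it does not leak into the primary-to-metastatic contrast).
#' TNM codes are generated consistently with cohort
#' membership (normals T0/N0/M0; primaries T1-T3, N0, M0; metastatic any T,
#' N1-N3, M0/M1), plus a fraction of extra tumour samples carrying a
#' TX/NX/MX code that downstream staging must exclude.
#'
#' @param genes character vector of gene symbols (the expression universe).
#' @param cfg a [synth_config()].
#' @param planted optional data frame (`gene`, `transition`, `log2fc`)
#'   overriding the planting derived from `cfg` (use
#'   `planted = data.frame()` for a null study).
#' @return An [expression_study()] (cohorts not yet built).
#' @export
synth_expression <- function(genes, cfg, planted = NULL) {
  stopifnot(inherits(cfg, "synth_config"), length(genes) >= 1)
  withr::with_seed(derive_seed(cfg$seed, 3), {
    ng <- length(genes)
    sizes <- cfg$cohort_sizes
    mats <- list(); mds <- list()
    for (ct in cfg$cancer_types) {
      meanlog <- stats::rnorm(ng, cfg$fpkm_logmean, 0.5)
      ids <- c(sprintf("%s_NORM%03d", ct, seq_len(sizes[["normal"]])),
               sprintf("%s_PRIM%03d", ct, seq_len(sizes[["primary"]])),
               sprintf("%s_MET%03d", ct, seq_len(sizes[["metastatic"]])))
      cohort_of <- rep(c("normal", "primary", "metastatic"),
                       times = sizes[c("normal", "primary", "metastatic")])
      n_extra <- round(cfg$missing_tnm_fraction * length(ids))
      if (n_extra > 0) {
        ids <- c(ids, sprintf("%s_MISS%03d", ct, seq_len(n_extra)))
        cohort_of <- c(cohort_of, rep("missing", n_extra))
      }
      m <- matrix(stats::rlnorm(ng * length(ids), meanlog = meanlog,
                                sdlog = cfg$fpkm_logsd),
                  nrow = ng, ncol = length(ids),
                  dimnames = list(genes, ids))
      tnm <- data.frame(
        T = character(length(ids)), N = character(length(ids)),
        M = character(length(ids)), stringsAsFactors = FALSE)
      src <- ifelse(cohort_of == "normal", "normal", "tumour")
      tnm$T[cohort_of == "normal"] <- "T0"
      tnm$N[cohort_of == "normal"] <- "N0"
      tnm$M[cohort_of == "normal"] <- "M0"
      np <- sum(cohort_of == "primary")
      tnm$T[cohort_of == "primary"] <- sample(c("T1", "T2", "T3"), np, TRUE)
      tnm$N[cohort_of == "primary"] <- "N0"
      tnm$M[cohort_of == "primary"] <- "M0"
      nm <- sum(cohort_of == "metastatic")
      tnm$T[cohort_of == "metastatic"] <- sample(c("T1", "T2", "T3", "T4"), nm, TRUE)
      tnm$N[cohort_of == "metastatic"] <- sample(c("N1", "N2", "N3"), nm, TRUE)
      tnm$M[cohort_of == "metastatic"] <- sample(c("M0", "M1"), nm, TRUE)
      miss_idx <- which(cohort_of == "missing")
      if (length(miss_idx) > 0) {
        tnm$T[miss_idx] <- "T2"; tnm$N[miss_idx] <- "N0"; tnm$M[miss_idx] <- "M0"
        which_x <- sample(c("T", "N", "M"), length(miss_idx), TRUE)
        for (jj in seq_along(miss_idx)) {
          tnm[[which_x[jj]]][miss_idx[jj]] <- paste0(which_x[jj], "X")
        }
      }
      mats[[ct]] <- list(m = m, cohort_of = cohort_of)
      mds[[ct]] <- data.frame(sample_id = ids, cancer_type = ct,
                              source = src, T = tnm$T, N = tnm$N, M = tnm$M,
                              stringsAsFactors = FALSE)
    }
    if (is.null(planted)) {
      planted <- data.frame(gene = character(0), transition = character(0),
                            log2fc = numeric(0), stringsAsFactors = FALSE)
    }
    for (ct in cfg$cancer_types) {
      m <- mats[[ct]]$m; cohort_of <- mats[[ct]]$cohort_of
      for (r in seq_len(nrow(planted))) {
        gene <- planted$gene[r]
        if (!gene %in% rownames(m)) next
        # effects persist through later disease stages: a normal->primary
        # effect is present in both tumour cohorts, a primary->metastatic
        # effect only in the metastatic cohort
        later <- if (planted$transition[r] == "primary_metastatic")
          "metastatic" else c("primary", "metastatic")
        cols <- which(cohort_of %in% later)
        m[gene, cols] <- m[gene, cols] * 2^planted$log2fc[r]
      }
      mats[[ct]]$m <- m
    }
    full <- do.call(cbind, lapply(mats, `[[`, "m"))
    md <- do.call(rbind, mds)
    rownames(md) <- NULL
    expression_study(full, md)
  })
}

#' Generate a complete synthetic dataset
#'
#' Convenience orchestrator running [synth_network()],
#' [synth_annotations()] and [synth_expression()] with the planting implied
#' by the configuration (the `n_planted` protected genes receive
#' `planted_log2fc` on `planted_transition`).
#'
#' @param cfg a [synth_config()].
#' @return List with `network`, `pool`, `seed_genes`, `doid_map`,
#'   `planted` (data frame of planted effects plus `hub` / `specific`
#'   attributes), and `study`.
#' @export
synth_dataset <- function(cfg) {
  nets <- synth_network(cfg)
  ann <- synth_annotations(nets$network, cfg)
  planted <- data.frame(gene = ann$planted$expression_genes,
                        transition = cfg$planted_transition,
                        log2fc = cfg$planted_log2fc,
                        stringsAsFactors = FALSE)
  study <- synth_expression(network_nodes(nets$network), cfg, planted = planted)
  list(network = nets$network, pool = nets$pool,
       seed_genes = ann$seed_genes, doid_map = ann$doid_map,
       planted = list(effects = planted, hub = ann$planted$hub,
                      specific = ann$planted$specific),
       study = study)
}

#' Write a full synthetic fixture set to disk
#'
#' Emits `net.tsv`, `pool.tsv`, `seeds.txt`, `doid.tsv`, `fpkm.tsv` and
#' `meta.tsv` under `outdir`, all readable by the package's own readers.
#' Output is byte-identical for a fixed configuration.
#'
#' @param cfg a [synth_config()].
#' @param outdir output directory (created if absent).
#' @return Named character vector of file paths, invisibly.
#' @export
write_synth_fixtures <- function(cfg, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  ds <- synth_dataset(cfg)
  paths <- c(net = file.path(outdir, "net.tsv"),
             pool = file.path(outdir, "pool.tsv"),
             seeds = file.path(outdir, "seeds.txt"),
             doid = file.path(outdir, "doid.tsv"),
             fpkm = file.path(outdir, "fpkm.tsv"),
             meta = file.path(outdir, "meta.tsv"))
  write_network_tsv(ds$network, paths[["net"]])
  utils::write.table(as.data.frame(ds$pool), paths[["pool"]], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  writeLines(ds$seed_genes, paths[["seeds"]])
  utils::write.table(ds$doid_map, paths[["doid"]], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  expr <- data.frame(gene = rownames(ds$study$matrix),
                     ds$study$matrix, check.names = FALSE,
                     stringsAsFactors = FALSE)
  utils::write.table(expr, paths[["fpkm"]], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(ds$study$metadata, paths[["meta"]], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(paths)
}
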