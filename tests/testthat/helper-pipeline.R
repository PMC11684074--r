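# one full synthetic prioritization + hit-calling run, used by the
# planted-recovery tests

run_planted_pipeline <- function(seed, cfg = synth_config(seed = seed)) {
  ds <- suppressMessages(synth_dataset(cfg))
  net <- suppressMessages(label_seeds(ds$network, ds$seed_genes))
  cands <- find_candidates(net)
  cands <- annotation_filter(cands, ds$doid_map)
  cands <- connectivity_filter(cands)
  hits <- suppressWarnings(suppressMessages(call_hits(cands, ds$study)))
  planted <- ds$planted$effects$gene
  pm <- hits[hits$transition == "primary_metastatic", , drop = FALSE]
  list(
    cands = cands,
    hits = hits,
    planted = planted,
    n_planted_hit = sum(pm$is_hit & pm$gene %in% planted),
    n_planted_high = sum(pm$tier == "high" & pm$gene %in% planted),
    n_false_hit = sum(pm$is_hit & !(pm$gene %in% planted)),
    hub_removed = cands$status[cands$symbol == ds$planted$hub] == "removed_connectivity",
    specific_final = cands$status[cands$symbol == ds$planted$specific] == "final")
}
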