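# 50-replicate planted-truth study under the default synthetic configuration,
# shared by the discrimination and energy-uniformity acceptance checks (run
# once per test session, both metrics computed from the same ensembles)

planted_truth_study <- local({
  cache <- NULL
  function(n_seeds = 50L) {
    if (!is.null(cache)) return(cache)
    rows <- lapply(seq_len(n_seeds), function(seed) {
      ens <- simulate_ensemble(synthetic_config(seed = seed))
      fps <- decoy_fingerprints(ens$decoys,
                                cutoff = ens$config$contact_cutoff,
                                receptor_length = ens$config$receptor_length,
                                ligand_length = ens$config$ligand_length)
      res <- discriminate_near_native(ens$decoys, ens$native_fp, fps = fps,
                                      k = 10)
      purity <- mean(ens$truth$planted[match(res$blind_members,
                                             ens$truth$decoy_id)] == "tight")
      prof <- group_sd_threshold_profile(ens$decoys, fps)
      data.frame(
        seed = seed, purity = purity, agreement = res$agreement,
        mean_sd_ifp = mean(prof$mean_group_sd[prof$method == "ifp"],
                           na.rm = TRUE),
        mean_sd_rmsd = mean(prof$mean_group_sd[prof$method == "rmsd"],
                            na.rm = TRUE))
    })
    cache <<- do.call(rbind, rows)
    cache
  }
})
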