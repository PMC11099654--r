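# shared synthetic families, generated once per test session
.fam_cache <- new.env(parent = emptyenv())

cached_family <- function(key, spec) {
  if (is.null(.fam_cache[[key]])) .fam_cache[[key]] <- generate_family(spec)
  .fam_cache[[key]]
}

# a 4-group family with strong within-group and weak between-group identity
# (planted clustering structure)
four_clade_family <- function() {
  cached_family("four_clade", family_spec(
    n_sequences = 20, n_clades = 4, within_identity = 0.9,
    between_identity = 0.25, architecture = bab_architecture(2),
    indel_rate = 0.2, tree = "star", seed = 42))
}

# mid-identity 2-clade family used across alignment/squeeze tests
two_clade_family <- function() {
  cached_family("two_clade", family_spec(
    n_sequences = 8, n_clades = 2, target_identity = 0.35,
    architecture = bab_architecture(2), indel_rate = 0.3, seed = 7))
}

# run the full pipeline on a written bundle; memoised per key
pipeline_run <- function(key, fam, ...) {
  rkey <- paste0("run_", key)
  if (is.null(.fam_cache[[rkey]])) {
    dir <- file.path(tempdir(), paste0("bundle_", key))
    if (!dir.exists(dir)) write_family_bundle(fam, dir)
    cfg <- pipeline_config(input = file.path(dir, "family.fasta"),
                           structures = dir,
                           output_dir = file.path(tempdir(),
                                                  paste0("out_", key)),
                           ...)
    .fam_cache[[rkey]] <- list(res = run_pipeline(cfg), cfg = cfg,
                               bundle = dir)
  }
  .fam_cache[[rkey]]
}
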