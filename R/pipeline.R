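#' Pipeline configuration
#'
#' All tunables of the end-to-end run. Thresholds are fractional identities;
#' the config round-trips losslessly through its YAML file form
#' ([read_config]/[write_config]).
#'
#' @param input path to the input multi-FASTA (required for [run_pipeline]).
#' @param structures optional directory of per-sequence structure files
#'   (`<id>.pdb`/`.cif`) and/or `<id>.ss.fasta` secondary-structure files.
#' @param output_dir run output directory.
#' @param redundancy_threshold identity cutoff of the cleaning step
#'   (default 0.9).
#' @param subset_threshold identity cutoff of subset creation (default 0.3).
#' @param min_subset_size minimum standalone subset size (default 2).
#' @param collate pool small clusters into subsets instead of labelling
#'   orphans (default TRUE).
#' @param max_unresolved_fraction exclusion threshold on unresolved residues
#'   (default 0.25).
#' @param squeeze enable the gap-squeezing step (default TRUE).
#' @param squeeze_categories secondary-structure categories driving the
#'   squeeze (default `c("H", "E")`).
#' @param squeeze_threshold column conservation threshold (default 0.8).
#' @param squeeze_min_block minimum conserved-block length (default 2).
#' @param ss_source `"auto"` (per-id `.ss.fasta` files when present, else
#'   geometric assignment from CA coordinates), `"files"`, or `"assign"`.
#' @param providers named list of structure fetchers for `afdb`/`esmf`
#'   routes (see [resolve_structures]); not serialised to YAML.
#' @param cores worker count for subset alignment (results are identical to
#'   sequential execution).
#' @param resume skip stages whose manifest exists with matching input
#'   hashes (default TRUE).
#' @param seed RNG seed recorded with the run.
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(input = NULL, structures = NULL,
                            output_dir = "foldmsa_run",
                            redundancy_threshold = 0.9,
                            subset_threshold = 0.3, min_subset_size = 2,
                            collate = TRUE, max_unresolved_fraction = 0.25,
                            squeeze = TRUE, squeeze_categories = c("H", "E"),
                            squeeze_threshold = 0.8, squeeze_min_block = 2,
                            ss_source = c("auto", "files", "assign"),
                            providers = list(), cores = 1, resume = TRUE,
                            seed = 1) {
  ss_source <- match.arg(ss_source)
  cfg <- list(input = input, structures = structures,
              output_dir = output_dir,
              redundancy_threshold = redundancy_threshold,
              subset_threshold = subset_threshold,
              min_subset_size = min_subset_size, collate = collate,
              max_unresolved_fraction = max_unresolved_fraction,
              squeeze = squeeze, squeeze_categories = squeeze_categories,
              squeeze_threshold = squeeze_threshold,
              squeeze_min_block = squeeze_min_block, ss_source = ss_source,
              providers = providers, cores = cores, resume = resume,
              seed = seed)
  validate_config(cfg)
  structure(cfg, class = "pipeline_config")
}

validate_config <- function(cfg) {
  chk <- function(x, lo, hi, nm) {
    if (!is.numeric(x) || x < lo || x > hi)
      stop("config error: ", nm, " must be in [", lo, ", ", hi, "]")
  }
  chk(cfg$redundancy_threshold, 0.2, 1, "redundancy_threshold")
  chk(cfg$subset_threshold, 0.2, 1, "subset_threshold")
  chk(cfg$max_unresolved_fraction, 0, 1, "max_unresolved_fraction")
  chk(cfg$squeeze_threshold, 1e-9, 1, "squeeze_threshold")
  if (cfg$min_subset_size < 2)
    stop("config error: min_subset_size must be >= 2")
  if (!all(cfg$squeeze_categories %in% c("H", "E")))
    stop("config error: squeeze_categories must be a subset of H, E")
  invisible(TRUE)
}

#' @rdname pipeline_config
#' @param path YAML file path.
#' @export
read_config <- function(path) {
  y <- yaml::read_yaml(path)
  y$providers <- list()
  do.call(pipeline_config, y)
}

#' @rdname pipeline_config
#' @param cfg a `pipeline_config`.
#' @export
write_config <- function(cfg, path) {
  y <- unclass(cfg)
  y$providers <- NULL
  yaml::write_yaml(y, path)
  invisible(path)
}

# --- stage manifests -----------------------------------------------------

manifest_path <- function(outdir, stage)
  file.path(outdir, "manifests", paste0(stage, ".json"))

hash_inputs <- function(files, extra = NULL) {
  files <- files[file.exists(files)]
  h <- as.list(tools::md5sum(files))
  if (!is.null(extra))
    h[["config"]] <- digest_string(jsonlite::toJSON(extra, auto_unbox = TRUE))
  h
}

# md5 of a string via a temp file (tools::md5sum is file-based)
digest_string <- function(x) {
  tf <- tempfile()
  writeLines(as.character(x), tf)
  on.exit(unlink(tf))
  unname(tools::md5sum(tf))
}

write_manifest <- function(outdir, stage, inputs, outputs, status = "done") {
  dir.create(file.path(outdir, "manifests"), showWarnings = FALSE,
             recursive = TRUE)
  jsonlite::write_json(list(stage = stage, inputs = inputs,
                            outputs = outputs, status = status,
                            finished = format(Sys.time(), usetz = TRUE)),
                       manifest_path(outdir, stage), auto_unbox = TRUE)
}

stage_current <- function(outdir, stage, inputs) {
  mp <- manifest_path(outdir, stage)
  if (!file.exists(mp)) return(FALSE)
  m <- jsonlite::read_json(mp)
  if (!identical(m$status, "done")) return(FALSE)
  if (!identical(lapply(m$inputs, as.character),
                 lapply(inputs, as.character))) return(FALSE)
  all(file.exists(unlist(m$outputs)))
}

run_stage <- function(cfg, stage, inputs, outputs, fn, log) {
  inputs <- hash_inputs(inputs, extra = stage_config(cfg, stage))
  if (cfg$resume && stage_current(cfg$output_dir, stage, inputs)) {
    log(sprintf("[%s] up to date, skipped", stage))
    return(invisible(FALSE))
  }
  log(sprintf("[%s] running", stage))
  ok <- tryCatch({ fn(); TRUE },
                 error = function(e) {
                   write_manifest(cfg$output_dir, stage, inputs,
                                  outputs, status = "failed")
                   stop("stage ", stage, " failed: ", conditionMessage(e),
                        call. = FALSE)
                 })
  write_manifest(cfg$output_dir, stage, inputs, outputs)
  invisible(TRUE)
}

# the config subset a stage depends on (changing an unrelated key must not
# invalidate the stage)
stage_config <- function(cfg, stage) {
  keys <- switch(stage,
    clean   = c("redundancy_threshold"),
    match   = c("max_unresolved_fraction", "ss_source"),
    subset  = c("subset_threshold", "min_subset_size", "collate"),
    align   = character(0),
    merge   = character(0),
    squeeze = c("squeeze", "squeeze_categories", "squeeze_threshold",
                "squeeze_min_block"),
    character(0))
  unclass(cfg)[keys]
}

# --- the pipeline --------------------------------------------------------

#' Run the structure-informed alignment pipeline end to end
#'
#' Executes clean (redundancy reduction) -> match (structure acquisition,
#' unresolved filter, secondary structure) -> subset (identity clustering)
#' -> align (structure-aware subset alignment, optionally parallel) ->
#' merge (shape-preserving) -> squeeze (optional) and writes
#' `final.aln.fasta` plus a per-sequence fate report. Each stage records a
#' manifest of its input hashes; re-running in the same output directory
#' skips stages whose inputs are unchanged. Results are deterministic for a
#' given config and independent of the worker count.
#'
#' @param cfg a [pipeline_config] with at least `input` set.
#' @param stages stages to execute (default: all, in order). Running a
#'   stage whose prerequisites are missing errors naming the required
#'   prior stage, so stages are independently scriptable.
#' @return (invisibly) list with `msa` (final [msa], NULL unless the
#'   squeeze stage ran), `report` (data frame: id, fate), and
#'   `output_dir`.
#' @export
run_pipeline <- function(cfg, stages = c("clean", "match", "subset",
                                         "align", "merge", "squeeze")) {
  stopifnot(inherits(cfg, "pipeline_config"),
            all(stages %in% c("clean", "match", "subset", "align",
                              "merge", "squeeze")))
  if (is.null(cfg$input) || !file.exists(cfg$input))
    stop("config error: input FASTA not found: ", cfg$input %||% "<NULL>")
  out <- cfg$output_dir
  for (d in c("", "01_clean", "02_match", "03_subset", "04_align",
              "05_merge", "06_squeeze", "manifests", "logs"))
    dir.create(file.path(out, d), recursive = TRUE, showWarnings = FALSE)
  logfile <- file.path(out, "logs", "run.log")
  log <- function(msg) {
    line <- paste0(format(Sys.time(), "%H:%M:%S "), msg)
    cat(line, "\n", sep = "", file = logfile, append = TRUE)
  }
  write_config(cfg, file.path(out, "config.yaml"))
  need <- function(files, prior) {
    files <- unlist(files)
    if (length(files) == 0L || !all(file.exists(files)))
      stop("missing outputs of stage '", prior, "'; run it first")
  }

  p <- list(
    cleaned   = file.path(out, "01_clean", "cleaned.fasta"),
    dropped   = file.path(out, "01_clean", "dropped.tsv"),
    match_rep = file.path(out, "02_match", "match_report.tsv"),
    ss        = file.path(out, "02_match", "ss.fasta"),
    orphans   = file.path(out, "03_subset", "orphans.txt"),
    sless     = file.path(out, "02_match", "structureless.txt"),
    merged    = file.path(out, "05_merge", "merged.aln.fasta"),
    origins   = file.path(out, "05_merge", "origins.tsv"),
    final     = file.path(out, "final.aln.fasta"),
    report    = file.path(out, "report.tsv"))

  # -- clean ---------------------------------------------------------------
  if ("clean" %in% stages)
  run_stage(cfg, "clean", cfg$input, c(p$cleaned, p$dropped), function() {
    records <- read_fasta(cfg$input)
    red <- reduce_redundancy(records, cfg$redundancy_threshold)
    write_fasta(records[match(red$kept, records$id), ], p$cleaned)
    write.table(data.frame(dropped = names(red$dropped),
                           kept = unname(red$dropped)),
                p$dropped, sep = "\t", quote = FALSE, row.names = FALSE)
    log(sprintf("[clean] kept %d / %d sequences", length(red$kept),
                nrow(records)))
  }, log)

  # -- match ---------------------------------------------------------------
  struct_files <- if (!is.null(cfg$structures))
    list.files(cfg$structures, full.names = TRUE) else character(0)
  if ("match" %in% stages) {
  need(p$cleaned, "clean")
  run_stage(cfg, "match", c(p$cleaned, struct_files),
            c(p$match_rep, p$ss, p$sless), function() {
    records <- read_fasta(p$cleaned)
    idx <- index_structure_dir(cfg$structures)
    plan <- plan_structure_acquisition(records, idx)
    res <- resolve_structures(records, plan, providers = cfg$providers)
    flt <- filter_unresolved(res$matched, cfg$max_unresolved_fraction)
    res$log$outcome[res$log$id %in% flt$excluded] <- "excluded_unresolved"
    res$log$unresolved_fraction <- vapply(res$log$id, function(id) {
      s <- res$matched[[id]]
      if (is.null(s)) NA_real_ else s$unresolved_fraction
    }, numeric(1))
    write.table(res$log, p$match_rep, sep = "\t", quote = FALSE,
                row.names = FALSE)
    writeLines(res$structureless, p$sless)
    ss <- pipeline_ss(flt$kept, records, cfg)
    write_ss_fasta(ss, p$ss)
    log(sprintf("[match] %d matched, %d structureless, %d excluded",
                length(flt$kept), length(res$structureless),
                length(flt$excluded)))
  }, log)
  }

  # -- subset --------------------------------------------------------------
  if ("subset" %in% stages) {
  need(c(p$cleaned, p$match_rep), "match")
  run_stage(cfg, "subset", c(p$cleaned, p$match_rep), p$orphans, function() {
    st <- read_match_state(p, cfg)
    matched_rec <- st$records[st$records$id %in% st$matched_ids, ,
                              drop = FALSE]
    if (nrow(matched_rec) < 2)
      stop("fewer than 2 sequences matched to structures; ",
           "structure-informed subsetting is not possible")
    cs <- greedy_cluster(matched_rec, cfg$subset_threshold)
    sub <- make_subsets(cs, cfg$min_subset_size, cfg$collate)
    old <- list.files(file.path(out, "03_subset"),
                      pattern = "^subset_\\d+\\.txt$", full.names = TRUE)
    unlink(old)
    for (k in seq_along(sub$subsets))
      write_id_list(sub$subsets[[k]],
                    file.path(out, "03_subset", sprintf("subset_%03d.txt", k)))
    write_id_list(sub$orphans, p$orphans)
    log(sprintf("[subset] %d subsets, %d orphans", length(sub$subsets),
                length(sub$orphans)))
  }, log)
  }

  subset_files <- function() sort(list.files(file.path(out, "03_subset"),
                                             pattern = "^subset_\\d+\\.txt$",
                                             full.names = TRUE))

  # -- align ---------------------------------------------------------------
  if ("align" %in% stages) {
  need(c(p$ss, subset_files()), "subset")
  run_stage(cfg, "align", c(p$cleaned, p$ss, subset_files()),
            file.path(out, "04_align",
                      sub("\\.txt$", ".aln.fasta", basename(subset_files()))),
            function() {
    st <- read_match_state(p, cfg)
    ss_map <- read_ss_fasta(p$ss)
    files <- subset_files()
    old <- list.files(file.path(out, "04_align"), full.names = TRUE)
    unlink(old)
    align_one <- function(f) {
      ids <- read_id_list(f)
      m <- align_subset(st$records[match(ids, st$records$id), , drop = FALSE],
                        st$structures[ids], ss_map[ids])
      out_f <- file.path(out, "04_align",
                         sub("\\.txt$", ".aln.fasta", basename(f)))
      write_msa(m, out_f)
      out_f
    }
    if (cfg$cores > 1) {
      res <- parallel::mclapply(files, align_one, mc.cores = cfg$cores)
      err <- vapply(res, inherits, logical(1), "try-error")
      if (any(err)) stop(res[[which(err)[1]]])
    } else lapply(files, align_one)
    log(sprintf("[align] %d subsets aligned", length(files)))
  }, log)
  }

  aln_files <- function() sort(list.files(file.path(out, "04_align"),
                                          pattern = "\\.aln\\.fasta$",
                                          full.names = TRUE))

  # -- merge ---------------------------------------------------------------
  if ("merge" %in% stages) {
  need(aln_files(), "align")
  run_stage(cfg, "merge", c(aln_files(), p$orphans, p$sless),
            c(p$merged, p$origins), function() {
    st <- read_match_state(p, cfg)
    msas <- lapply(aln_files(), read_msa)
    orphan_ids <- read_id_list(p$orphans)
    sless_ids <- read_id_list(p$sless)
    ss_map <- read_ss_fasta(p$ss)
    merged <- merge_all(msas,
                        orphans = st$records[st$records$id %in% orphan_ids, ,
                                             drop = FALSE],
                        structureless = st$records[st$records$id %in% sless_ids, ,
                                                   drop = FALSE],
                        ss_map = ss_map,
                        coords = common_frame_coords(st$records,
                                                     st$structures, ss_map),
                        pair_loops = FALSE)
    write_msa(merged$msa, p$merged)
    write.table(merged$origins, p$origins, sep = "\t", quote = FALSE,
                row.names = FALSE)
    log(sprintf("[merge] %d sequences, width %d", msa_nrow(merged$msa),
                msa_width(merged$msa)))
  }, log)
  }

  # -- squeeze + report ----------------------------------------------------
  if ("squeeze" %in% stages) {
  need(c(p$merged, p$origins), "merge")
  run_stage(cfg, "squeeze", c(p$merged, p$ss), c(p$final, p$report),
            function() {
    m <- read_msa(p$merged)
    if (cfg$squeeze) {
      ss_map <- read_ss_fasta(p$ss)
      ann <- annotate_columns(m, ss_map,
                              categories = cfg$squeeze_categories,
                              threshold = cfg$squeeze_threshold,
                              min_block = cfg$squeeze_min_block)
      sq <- squeeze_msa(m, ann)
      log(sprintf("[squeeze] width %d -> %d, gaps %d -> %d", msa_width(m),
                  msa_width(sq), msa_gap_count(m), msa_gap_count(sq)))
      m <- sq
    } else log("[squeeze] disabled")
    write_msa(m, p$final)
    write_run_report(cfg, p)
  }, log)
  }

  final <- if (file.exists(p$final)) read_msa(p$final) else NULL
  report <- if (file.exists(p$report))
    read.table(p$report, sep = "\t", header = TRUE,
               stringsAsFactors = FALSE) else NULL
  invisible(list(msa = final, report = report, output_dir = out))
}

# secondary structure for the matched set, per config ss_source
pipeline_ss <- function(kept_structures, records, cfg) {
  lapply_named <- function(ids, f) { r <- lapply(ids, f); names(r) <- ids; r }
  lapply_named(names(kept_structures), function(id) {
    if (cfg$ss_source != "assign" && !is.null(cfg$structures)) {
      f <- file.path(cfg$structures, paste0(id, ".ss.fasta"))
      if (file.exists(f)) return(read_ss_fasta(f)[[1]])
      if (cfg$ss_source == "files")
        stop("ss_source = files but no ss file for ", id)
    }
    assign_ss(kept_structures[[id]])
  })
}

# reload cleaned records + structures from the paths in the match report
read_match_state <- function(p, cfg) {
  records <- read_fasta(p$cleaned)
  mrep <- read.table(p$match_rep, sep = "\t", header = TRUE,
                     stringsAsFactors = FALSE)
  matched <- mrep[mrep$outcome == "matched", , drop = FALSE]
  structures <- lapply(seq_len(nrow(matched)), function(i)
    read_structure(matched$path[i],
                   records$residues[records$id == matched$id[i]],
                   id = matched$id[i]))
  names(structures) <- matched$id
  list(records = records, matched_ids = matched$id, structures = structures,
       report = mrep)
}

write_run_report <- function(cfg, p) {
  records <- read_fasta(cfg$input)
  fate <- rep(NA_character_, nrow(records))
  names(fate) <- records$id
  dropped <- tryCatch(read.table(p$dropped, sep = "\t", header = TRUE,
                                 stringsAsFactors = FALSE),
                      error = function(e) data.frame())
  if (nrow(dropped))
    fate[dropped$dropped] <- paste0("dropped_redundant:", dropped$kept)
  mrep <- read.table(p$match_rep, sep = "\t", header = TRUE,
                     stringsAsFactors = FALSE)
  fate[mrep$id[mrep$outcome == "excluded_unresolved"]] <- "excluded_unresolved"
  origins <- read.table(p$origins, sep = "\t", header = TRUE,
                        stringsAsFactors = FALSE)
  fate[origins$id] <- origins$origin
  write.table(data.frame(id = records$id, fate = unname(fate[records$id])),
              p$report, sep = "\t", quote = FALSE, row.names = FALSE)
}
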