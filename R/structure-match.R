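# normalise a name for sequence<->file matching: basename, strip structure
# extensions, case-fold
normalize_struct_name <- function(x) {
  x <- basename(x)
  x <- sub("\\.(pdb|cif|mmcif|ent)$", "", x, ignore.case = TRUE)
  tolower(x)
}

#' Index a directory of per-sequence structure files
#'
#' @param dir directory containing `.pdb` / `.cif` / `.mmcif` files named by
#'   sequence id (extension stripped, case-insensitive match).
#' @return named character vector: normalised id -> file path.
#' @export
index_structure_dir <- function(dir) {
  if (is.null(dir) || !dir.exists(dir)) return(character(0))
  files <- list.files(dir, pattern = "\\.(pdb|cif|mmcif|ent)$",
                      ignore.case = TRUE, full.names = TRUE)
  out <- files
  names(out) <- normalize_struct_name(files)
  out[!duplicated(names(out))]
}

#' Plan structure acquisition for a set of sequences
#'
#' Routing, per record: a user-provided file if one matches the id; else the
#' AlphaFold database when a UniProt accession was parsed from the header;
#' else a fold-prediction service for sequences shorter than 400 residues;
#' else none (the sequence will become structureless).
#'
#' @param records a `seq_records` data frame.
#' @param user_index named path vector from [index_structure_dir] (may be
#'   empty).
#' @return data frame with columns `seq_id`, `uniprot_id`, `length`, `route`
#'   (one of `user_file`, `afdb`, `esmf`, `none`) and `path` (user files).
#' @export
plan_structure_acquisition <- function(records, user_index = character(0)) {
  norm_ids <- vapply(records$id, normalize_struct_name, character(1),
                     USE.NAMES = FALSE)
  hit <- unname(user_index[norm_ids])
  len <- nchar(records$residues)
  route <- ifelse(!is.na(hit), "user_file",
           ifelse(!is.na(records$uniprot_id), "afdb",
           ifelse(len < 400, "esmf", "none")))
  data.frame(seq_id = records$id, uniprot_id = records$uniprot_id,
             length = len, route = route,
             path = ifelse(route == "user_file", hit, NA_character_),
             stringsAsFactors = FALSE)
}

#' Resolve structures for all planned requests
#'
#' Acquisition is best-effort: every record ends up either matched (its file
#' passed [read_structure] validation against the record's sequence) or
#' structureless, with the reason logged; provider failures never abort the
#' run. Providers are pluggable: a named list mapping a route (`afdb`,
#' `esmf`) to `function(request, record) -> structure file path`. Local
#' directory doubles satisfy the same contract as live fetchers.
#'
#' @param records `seq_records`.
#' @param plan output of [plan_structure_acquisition].
#' @param providers named list of fetchers for non-user routes (default:
#'   none, so `afdb`/`esmf` routes fall through to structureless).
#' @param chain optional chain id passed to [read_structure].
#' @return list with `matched` (named list of `chain_structure`),
#'   `structureless` (ids), `log` (data frame: id, route, outcome, detail).
#' @export
resolve_structures <- function(records, plan, providers = list(),
                               chain = NULL) {
  matched <- list()
  structureless <- character(0)
  log <- vector("list", nrow(plan))
  for (i in seq_len(nrow(plan))) {
    id <- plan$seq_id[i]
    rec <- records[records$id == id, ]
    route <- plan$route[i]
    path <- NULL
    outcome <- "structureless"; detail <- ""
    if (route == "user_file") {
      path <- plan$path[i]
    } else if (route %in% names(providers)) {
      path <- tryCatch(providers[[route]](plan[i, ], rec),
                       error = function(e) { detail <<- conditionMessage(e); NULL })
    } else if (route != "none") {
      detail <- paste0("no provider configured for route ", route)
    } else detail <- "no structure source"
    if (!is.null(path)) {
      st <- tryCatch(read_structure(path, rec$residues, chain = chain, id = id),
                     error = function(e) { detail <<- conditionMessage(e); NULL })
      if (!is.null(st)) {
        matched[[id]] <- st
        outcome <- "matched"
      }
    }
    if (outcome != "matched") structureless <- c(structureless, id)
    log[[i]] <- data.frame(id = id, route = route, outcome = outcome,
                           detail = detail,
                           path = if (outcome == "matched") path
                                  else NA_character_,
                           stringsAsFactors = FALSE)
  }
  list(matched = matched, structureless = structureless,
       log = do.call(rbind, log))
}

#' Exclude structures with too many unresolved residues
#'
#' @param matched named list of `chain_structure` objects.
#' @param max_unresolved_fraction structures whose unresolved fraction
#'   exceeds this are excluded from the run (default 0.25).
#' @return list with `kept` (named list) and `excluded` (ids).
#' @export
filter_unresolved <- function(matched, max_unresolved_fraction = 0.25) {
  stopifnot(max_unresolved_fraction >= 0, max_unresolved_fraction <= 1)
  fr <- vapply(matched, function(s) s$unresolved_fraction, numeric(1))
  excluded <- names(matched)[fr > max_unresolved_fraction]
  list(kept = matched[setdiff(names(matched), excluded)], excluded = excluded)
}
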