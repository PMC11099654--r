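# collapse 8-state DSSP codes to 3 states: helices (H,G,I) -> H,
# strands/bridges (E,B) -> E, everything else (incl. PP-helix 'P') -> C
collapse_dssp <- function(code) {
  ifelse(code %in% c("H", "G", "I"), "H",
  ifelse(code %in% c("E", "B"), "E", "C"))
}

#' Parse a classic DSSP output file to a 3-state string
#'
#' Reads the fixed-column residue table of a classic `mkdssp` output file,
#' collapses the 8-state codes to `{H, E, C}` and maps them onto sequence
#' positions by residue number; positions without a DSSP record (unresolved)
#' are `C`.
#'
#' @param path DSSP file.
#' @param seq_id id to store on the result.
#' @param length sequence length; when NULL the highest residue number seen
#'   is used.
#' @param chain chain id filter (default: all records).
#' @return an `ss_string`: list with `id` and `states` (string over H/E/C).
#' @export
parse_dssp <- function(path, seq_id, length = NULL, chain = NULL) {
  lines <- readLines(path)
  hdr <- grep("^  #  RESIDUE", lines)
  if (length(hdr) != 1L)
    stop("malformed DSSP file (no residue table header): ", path)
  body <- lines[seq(hdr + 1L, length(lines))]
  body <- body[nchar(body) >= 17]
  aa <- substr(body, 14, 14)
  body <- body[aa != "!"]                       # chain breaks
  if (length(body) == 0L)
    return(ss_string(seq_id, strrep("C", length %||% 0L)))
  resno <- suppressWarnings(as.integer(substr(body, 6, 10)))
  ch <- substr(body, 12, 12)
  ss <- collapse_dssp(substr(body, 17, 17))
  keep <- !is.na(resno)
  if (!is.null(chain)) keep <- keep & ch == chain
  resno <- resno[keep]; ss <- ss[keep]
  L <- length %||% max(resno, 0L)
  states <- rep("C", L)
  ok <- resno >= 1 & resno <= L
  states[resno[ok]] <- ss[ok]
  ss_string(seq_id, paste0(states, collapse = ""))
}

#' Secondary-structure string constructor
#' @param id sequence id.
#' @param states string over `{H, E, C}` parallel to the sequence.
#' @return an `ss_string`.
#' @export
ss_string <- function(id, states) {
  if (grepl("[^HEC]", states)) stop("ss states must be over {H, E, C}")
  structure(list(id = id, states = states), class = "ss_string")
}

#' Assign 3-state secondary structure from CA coordinates
#'
#' A P-SEA-style geometric assignment on the CA trace. Position `i` is
#' helix-compatible when the CA(i)-CA(i+3) and CA(i)-CA(i+4) distances fall
#' in the canonical alpha-helix windows (5.5 +/- 0.5 A and 6.4 +/- 0.6 A);
#' strand-compatible when CA(i)-CA(i+2) is 6.7 +/- 0.6 A and the backbone is
#' locally straight (CA(i-1),CA(i),CA(i+1) angle >= 120 degrees). Runs of at
#' least 5 consecutive helix-compatible positions are called H over their
#' full window span (i..i+4); runs of at least 3 strand-compatible positions
#' are called E over i..i+2. H takes precedence; everything else, including
#' unresolved positions, is C. Chain termini lacking window partners relax
#' to C unless covered by a qualifying run's window span.
#'
#' @param chain a `chain_structure` (CA coordinates; at least 5 resolved
#'   positions for any non-C call).
#' @return an `ss_string` of the same length as the sequence.
#' @export
assign_ss <- function(chain) {
  L <- chain$length
  xyz <- chain$ca
  states <- rep("C", L)
  if (sum(chain$resolved_mask) < 5)
    return(ss_string(chain$id, paste0(states, collapse = "")))
  d <- function(i, j) sqrt(rowSums((xyz[i, , drop = FALSE] -
                                    xyz[j, , drop = FALSE])^2))
  ang <- function(a, b, cc) {       # angle at b in degrees
    v1 <- xyz[a, , drop = FALSE] - xyz[b, , drop = FALSE]
    v2 <- xyz[cc, , drop = FALSE] - xyz[b, , drop = FALSE]
    cosv <- rowSums(v1 * v2) / (sqrt(rowSums(v1^2)) * sqrt(rowSums(v2^2)))
    acos(pmin(pmax(cosv, -1), 1)) * 180 / pi
  }
  helix_ok <- rep(FALSE, L)
  if (L >= 5) {
    i <- seq_len(L - 4)
    d13 <- d(i, i + 3); d14 <- d(i, i + 4)
    helix_ok[i] <- !is.na(d13) & !is.na(d14) &
      d13 >= 5.0 & d13 <= 6.0 & d14 >= 5.8 & d14 <= 7.0
  }
  strand_ok <- rep(FALSE, L)
  if (L >= 3) {
    i <- seq_len(L - 2)
    d12 <- d(i, i + 2)
    straight <- rep(NA_real_, L)
    if (L >= 3) {
      m <- 2:(L - 1)
      straight[m] <- ang(m - 1, m, m + 1)
    }
    # straightness at i where defined, else fall back to the angle at i+1
    st <- ifelse(!is.na(straight[i]), straight[i], straight[i + 1])
    strand_ok[i] <- !is.na(d12) & !is.na(st) &
      d12 >= 6.1 & d12 <= 7.3 & st >= 120
  }
  mark_runs <- function(ok, min_run, span, label) {
    r <- rle(ok)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    for (k in which(r$values & r$lengths >= min_run)) {
      to <- min(ends[k] + span, L)
      idx <- starts[k]:to
      idx <- idx[states[idx] == "C"]
      states[idx] <<- label
    }
  }
  mark_runs(helix_ok, 5L, 4L, "H")
  mark_runs(strand_ok, 3L, 2L, "E")
  ss_string(chain$id, paste0(states, collapse = ""))
}

#' Write/read secondary-structure strings as FASTA-like files
#'
#' @param ss list of `ss_string` objects (or a single one).
#' @param path output `.ss.fasta` path.
#' @export
write_ss_fasta <- function(ss, path) {
  if (inherits(ss, "ss_string")) ss <- list(ss)
  v <- vapply(ss, function(s) s$states, character(1))
  names(v) <- vapply(ss, function(s) s$id, character(1))
  write_fasta(v, path)
}

#' @rdname write_ss_fasta
#' @return `read_ss_fasta`: named list of `ss_string`.
#' @export
read_ss_fasta <- function(path) {
  set <- Biostrings::readBStringSet(path)
  ids <- sub("\\s.*$", "", names(set))
  out <- Map(ss_string, ids, toupper(as.character(set)))
  names(out) <- ids
  out
}
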