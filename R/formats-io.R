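# UniProt accession pattern (both "db|ACC|name" and bare-accession headers)
UNIPROT_RE <- "^[OPQ][0-9][A-Z0-9]{3}[0-9]$|^[A-NR-Z][0-9]([A-Z][A-Z0-9]{2}[0-9]){1,2}$"

#' Read protein sequences from a FASTA file
#'
#' Sequence ids are the first whitespace-delimited token of each header and
#' must be unique. Residues are uppercased; gap characters (`-`, `.`) and any
#' character outside the 20 standard amino acids plus X are stripped with a
#' warning naming the record. A UniProt accession is extracted from headers of
#' the form `db|ACC|name` or from a bare-accession id.
#'
#' @param path path to a FASTA file with at least one record.
#' @return a `seq_records` data frame with columns `id`, `description`,
#'   `residues`, `uniprot_id` (NA when absent) and `status` (initially
#'   `"unmatched"`).
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0L) stop("no sequences in ", path)
  headers <- names(set)
  ids <- sub("\\s.*$", "", headers)
  if (anyDuplicated(ids))
    stop("duplicate sequence id: ", ids[duplicated(ids)][1])
  desc <- sub("^\\S+\\s*", "", headers)
  residues <- toupper(as.character(set))
  alpha_re <- paste0("[^", paste(AA_ALPHABET, collapse = ""), "]")
  cleaned <- gsub(alpha_re, "", residues)
  changed <- cleaned != residues
  for (i in which(changed))
    warning("record ", ids[i], ": stripped ",
            nchar(residues[i]) - nchar(cleaned[i]),
            " non-standard or gap character(s)", call. = FALSE)
  if (any(cleaned == ""))
    stop("record ", ids[cleaned == ""][1], " has no residues after cleaning")
  uniprot <- vapply(ids, function(id) {
    parts <- strsplit(id, "|", fixed = TRUE)[[1]]
    cand <- if (length(parts) >= 2) parts[2] else id
    if (grepl(UNIPROT_RE, cand)) cand else NA_character_
  }, character(1), USE.NAMES = FALSE)
  out <- data.frame(id = ids, description = desc, residues = cleaned,
                    uniprot_id = uniprot, status = "unmatched",
                    stringsAsFactors = FALSE)
  class(out) <- c("seq_records", "data.frame")
  out
}

#' Write sequences to FASTA
#'
#' @param x a `seq_records` data frame or a named character vector.
#' @param path output path.
#' @param width line-wrap width (canonical 60).
#' @export
write_fasta <- function(x, path, width = 60) {
  if (is.data.frame(x)) {
    seqs <- x$residues
    names(seqs) <- x$id
  } else seqs <- x
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_along(seqs)) {
    writeLines(paste0(">", names(seqs)[i]), con)
    s <- seqs[[i]]
    starts <- seq(1, max(nchar(s), 1), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1, nchar(s))), con)
  }
  invisible(path)
}

#' Read a multiple sequence alignment from FASTA
#'
#' Rows must have identical gapped length; `.` gaps are normalised to `-` and
#' residues uppercased. Columns that are all-gap are dropped so the returned
#' object satisfies the `msa` invariants.
#'
#' @param path FASTA alignment file.
#' @return an [msa] object.
#' @export
read_msa <- function(path) {
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0L) stop("no sequences in ", path)
  ids <- sub("\\s.*$", "", names(set))
  if (anyDuplicated(ids))
    stop("duplicate sequence id: ", ids[duplicated(ids)][1])
  rows <- chartr(".", "-", toupper(as.character(set)))
  names(rows) <- ids
  lens <- nchar(rows)
  if (length(unique(lens)) > 1)
    stop("ragged alignment rows: ",
         paste(ids, lens, sep = "=", collapse = ", "))
  drop_allgap_columns(msa(rows))
}

#' Write an alignment to FASTA
#'
#' All-gap columns are dropped on write; output is canonical (uppercase,
#' 60-column wrapping) so write/read round-trips are byte-stable.
#'
#' @param m an [msa].
#' @param path output path.
#' @export
write_msa <- function(m, path) {
  m <- drop_allgap_columns(m)
  write_fasta(m$rows, path, width = 60)
}

#' Read a subset membership file (one sequence id per line)
#' @param path text file.
#' @return character vector of ids.
#' @export
read_id_list <- function(path) {
  x <- readLines(path)
  x <- trimws(x)
  x[nzchar(x)]
}

#' @rdname read_id_list
#' @param ids character vector.
#' @export
write_id_list <- function(ids, path) {
  writeLines(ids, path)
  invisible(path)
}

# one-letter codes from bio3d's three-letter table; unknowns -> X
aa_three_to_one <- function(resid) {
  one <- suppressWarnings(bio3d::aa321(resid))
  one[is.na(one) | !(one %in% AA_ALPHABET)] <- "X"
  one
}

# global alignment of two residue strings under identity scoring; returns the
# Biostrings alignment object
identity_align <- function(a, b) {
  mat <- outer(AA_ALPHABET, AA_ALPHABET, function(x, y) ifelse(x == y, 1, 0))
  dimnames(mat) <- list(AA_ALPHABET, AA_ALPHABET)
  Biostrings::pairwiseAlignment(a, b, type = "global",
                                substitutionMatrix = mat,
                                gapOpening = 1, gapExtension = 0.5)
}

#' Read backbone coordinates from a PDB or mmCIF file
#'
#' Extracts the CA trace (plus N and C where present) of one polypeptide
#' chain, derives its one-letter sequence from residue names (non-standard
#' residues map to their parent code via the bio3d table, unknowns to X), and
#' maps the structure onto `expected_sequence` by global alignment with
#' identity scoring. Residue numbering is used only as a tie-breaking hint;
#' the alignment is authoritative.
#'
#' @param path PDB (`.pdb`) or mmCIF (`.cif`, `.mmcif`) file.
#' @param expected_sequence the residue string of the matching sequence
#'   record.
#' @param chain chain identifier; default: first polymer chain in file order
#'   (single-chain predicted models dominate the intended inputs).
#' @param id id to store on the result (defaults to the file base name).
#' @return a `chain_structure`: list with `id`, `length` (= expected sequence
#'   length), `resolved_mask` (logical per sequence position), `ca` (length x
#'   3 matrix, NA rows at unresolved positions), optional `n`/`c` matrices,
#'   `unresolved_fraction`, and `struct_sequence`.
#' @export
read_structure <- function(path, expected_sequence, chain = NULL, id = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  ext <- tolower(tools::file_ext(path))
  pdb <- if (ext %in% c("cif", "mmcif")) bio3d::read.cif(path)
         else bio3d::read.pdb(path)
  at <- pdb$atom
  if (is.null(chain)) chain <- at$chain[1]
  at <- at[at$chain %in% chain & at$elety %in% c("CA", "N", "C"), , drop = FALSE]
  ca <- at[at$elety == "CA", , drop = FALSE]
  if (nrow(ca) == 0L) stop("no CA atoms in ", path, " chain ", chain)
  # alt-loc: keep the highest-occupancy CA per residue
  key <- paste(ca$resno, ca$insert)
  if (anyDuplicated(key)) {
    ord <- order(match(key, unique(key)), -ca$o)
    ca <- ca[ord, , drop = FALSE]
    ca <- ca[!duplicated(paste(ca$resno, ca$insert)), , drop = FALSE]
  }
  struct_seq <- paste0(aa_three_to_one(ca$resid), collapse = "")

  aln <- identity_align(struct_seq, expected_sequence)
  sa <- chars(as.character(Biostrings::alignedPattern(aln)))
  se <- chars(as.character(Biostrings::alignedSubject(aln)))
  L <- nchar(expected_sequence)
  mask <- logical(L)
  struct_of <- integer(L)          # structure residue index per seq position
  ip <- 0L; ie <- 0L; n_id <- 0L; n_pair <- 0L
  for (k in seq_along(sa)) {
    if (sa[k] != GAP) ip <- ip + 1L
    if (se[k] != GAP) ie <- ie + 1L
    if (sa[k] != GAP && se[k] != GAP) {
      mask[ie] <- TRUE
      struct_of[ie] <- ip
      n_pair <- n_pair + 1L
      if (sa[k] == se[k]) n_id <- n_id + 1L
    }
  }
  if (n_pair == 0L || n_id / n_pair < 0.95)
    stop("structure mismatch: ", path, " identity ",
         round(if (n_pair) n_id / n_pair else 0, 3),
         " over resolved positions (< 0.95)")

  coords <- matrix(NA_real_, L, 3)
  coords[mask, ] <- as.matrix(ca[struct_of[mask], c("x", "y", "z")])
  res_key <- paste(ca$resno, ca$insert)
  pick_bb <- function(ety) {
    bb <- at[at$elety == ety, , drop = FALSE]
    if (nrow(bb) == 0L) return(NULL)
    bb <- bb[!duplicated(paste(bb$resno, bb$insert)), , drop = FALSE]
    m <- match(res_key[struct_of[mask]], paste(bb$resno, bb$insert))
    out <- matrix(NA_real_, L, 3)
    ok <- !is.na(m)
    out[which(mask)[ok], ] <- as.matrix(bb[m[ok], c("x", "y", "z")])
    out
  }
  structure(list(id = id %||% tools::file_path_sans_ext(basename(path)),
                 length = L, resolved_mask = mask, ca = coords,
                 n = pick_bb("N"), c = pick_bb("C"),
                 unresolved_fraction = 1 - sum(mask) / L,
                 struct_sequence = struct_seq),
            class = "chain_structure")
}

#' @export
print.chain_structure <- function(x, ...) {
  cat(sprintf("chain_structure %s: %d positions, %d resolved (%.1f%% unresolved)\n",
              x$id, x$length, sum(x$resolved_mask),
              100 * x$unresolved_fraction))
  invisible(x)
}

#' Build a chain_structure from in-memory coordinates
#'
#' Used by the synthetic family generator and anywhere coordinates are
#' produced programmatically rather than read from a file.
#'
#' @param id sequence id.
#' @param ca length x 3 CA coordinate matrix (NA rows = unresolved).
#' @return a `chain_structure`.
#' @export
chain_structure <- function(id, ca) {
  mask <- !is.na(ca[, 1])
  structure(list(id = id, length = nrow(ca), resolved_mask = mask,
                 ca = ca, n = NULL, c = NULL,
                 unresolved_fraction = 1 - sum(mask) / nrow(ca),
                 struct_sequence = NULL),
            class = "chain_structure")
}

#' Write a CA-trace PDB file
#'
#' Writes the resolved CA positions of a `chain_structure` as a single-chain
#' PDB file (one CA atom per residue), e.g. for the synthetic fixture bundle.
#'
#' @param chain a `chain_structure`.
#' @param sequence residue string (one-letter) giving residue names.
#' @param path output path.
#' @export
write_ca_pdb <- function(chain, sequence, path) {
  res <- chars(sequence)
  keep <- which(chain$resolved_mask)
  three <- bio3d::aa123(res[keep])
  three[is.na(three)] <- "UNK"
  bio3d::write.pdb(file = path,
                   xyz = as.vector(t(chain$ca[keep, , drop = FALSE])),
                   resno = keep, resid = three, elety = rep("CA", length(keep)),
                   chain = rep("A", length(keep)))
  invisible(path)
}
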