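# PDB / FASTA input-output and Ballesteros-Weinstein numbering.

#' Read a PDB file into helix atom tables
#'
#' Parsing is delegated to [bio3d::read.pdb()] after a light structural check
#' of every ATOM record.  Alternate locations are resolved deterministically:
#' the first altloc of each atom is kept.  Multi-model files return the frame
#' list (one `helix` per MODEL) unless a single `model` is requested.
#'
#' @param path PDB file path.
#' @param model optional 1-based model number to extract from a multi-model
#'   file.
#' @param hetatm keep HETATM records (needed for ligand complexes); default
#'   `FALSE`.
#' @return a `helix` tibble for single-model files (or a named list of them,
#'   one per chain, when several chains are present); a list of `helix` frames
#'   for multi-model files.
#' @export
read_pdb <- function(path, model = NULL, hetatm = FALSE) {
  if (!file.exists(path)) abort(sprintf("no such file: %s", path))
  lines <- readLines(path, warn = FALSE)
  is_atom <- startsWith(lines, "ATOM") | startsWith(lines, "HETATM")
  for (ln in which(is_atom)) {
    l <- lines[ln]
    if (nchar(l) < 54 ||
        anyNA(suppressWarnings(as.numeric(c(substr(l, 31, 38),
                                            substr(l, 39, 46),
                                            substr(l, 47, 54)))))) {
      abort(sprintf("malformed ATOM record at line %d of %s", ln, path))
    }
  }
  n_models <- sum(startsWith(lines, "MODEL "))
  if (!any(startsWith(lines, "ATOM"))) {
    abort(sprintf("%s contains no ATOM records (empty structure)", path))
  }
  multi <- n_models > 1 && is.null(model)
  pdb <- bio3d::read.pdb(path, multi = multi, verbose = FALSE)
  at <- pdb$atom
  keep <- if (hetatm) rep(TRUE, nrow(at)) else at$type == "ATOM"
  # first altloc wins
  altkey <- paste(at$chain, at$resno, at$insert, at$elety)
  keep <- keep & !duplicated(altkey)
  if (!any(keep)) abort(sprintf("%s yields an empty structure", path))
  mk <- function(xyz_row) {
    m <- matrix(xyz_row, ncol = 3, byrow = TRUE)
    new_helix(tibble::tibble(
      residue_index = at$resno[keep],
      residue_name = at$resid[keep],
      chain = ifelse(is.na(at$chain[keep]), "A", at$chain[keep]),
      atom = at$elety[keep],
      element = element_of(at$elety[keep]),
      x = m[keep, 1], y = m[keep, 2], z = m[keep, 3]))
  }
  xyz <- pdb$xyz
  if (multi) {
    frames <- lapply(seq_len(nrow(xyz)), function(i) mk(xyz[i, ]))
    return(frames)
  }
  if (!is.null(model) && n_models > 1) {
    pdbm <- bio3d::read.pdb(path, multi = TRUE, verbose = FALSE)
    if (model < 1 || model > nrow(pdbm$xyz)) {
      abort(sprintf("model %d not in file (%d models)", model, nrow(pdbm$xyz)))
    }
    return(mk(pdbm$xyz[model, ]))
  }
  h <- mk(as.numeric(xyz))
  chains <- unique(h$chain)
  if (length(chains) > 1) {
    return(setNames(lapply(chains, function(cc) as_helix(h[h$chain == cc, ])),
                    chains))
  }
  h
}

format_atom_line <- function(serial, atom, resname, chain, resno, x, y, z,
                             element) {
  name_fmt <- if (nchar(atom) < 4) sprintf(" %-3s", atom) else sprintf("%-4s", atom)
  sprintf("ATOM  %5d %s %-3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          serial %% 100000, name_fmt, resname, chain, resno, x, y, z, 1, 0,
          element)
}

#' Write helix structures to a PDB file
#'
#' A single `helix` is written as a plain coordinate file; a list of frames is
#' written as a multi-model file with MODEL/ENDMDL records.  Coordinates are
#' written at the PDB's 3-decimal precision.
#'
#' @param h a `helix` or a list of `helix` frames sharing one topology.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_pdb <- function(h, path) {
  frames <- if (is_helix(h)) list(h) else h
  con <- file(path, "w")
  on.exit(close(con))
  multi <- length(frames) > 1
  for (fi in seq_along(frames)) {
    f <- as_helix(frames[[fi]])
    if (multi) writeLines(sprintf("MODEL     %4d", fi), con)
    writeLines(vapply(seq_len(nrow(f)), function(i) {
      format_atom_line(i, f$atom[i], f$residue_name[i], f$chain[i],
                       f$residue_index[i], f$x[i], f$y[i], f$z[i],
                       f$element[i])
    }, character(1)), con)
    if (multi) writeLines("ENDMDL", con) else writeLines("TER", con)
  }
  writeLines("END", con)
  invisible(path)
}

#' Read sequences from a FASTA file
#'
#' @param path FASTA file path.
#' @return a tibble with columns `name` and `sequence` (one-letter codes).
#' @export
read_fasta <- function(path) {
  fa <- bio3d::read.fasta(path)
  tibble::tibble(
    name = rownames(fa$ali),
    sequence = unname(apply(fa$ali, 1,
                            function(r) paste(r[r != "-"], collapse = ""))))
}

# ---- Ballesteros-Weinstein numbering --------------------------------------

#' Assign Ballesteros-Weinstein numbers
#'
#' Class A GPCR residues are labelled `helix.NN` with NN = 50 at the most
#' conserved residue of each transmembrane helix (the anchor); the residue k
#' positions before the anchor is `helix.(50-k)`, the one k after is
#' `helix.(50+k)`.  Residues outside every helix range keep only their
#' absolute sequence number, rendered like `R(220)`.
#'
#' @param sequence residue sequence: a one-letter string, a character vector
#'   of one- or three-letter codes, or a `helix` atom table.
#' @param anchors named integer vector or list mapping helix number
#'   (`"1"`..`"7"`) to the absolute index of its x.50 residue.  Two anchors
#'   for one helix is a configuration error.
#' @param ranges optional tibble/data.frame with columns `helix`, `start`,
#'   `end` delimiting each helix; by default each helix spans from the
#'   midpoint with its neighbouring anchor (sequence ends for the outermost).
#' @return a `bw_map` tibble: `residue_index`, `residue_name`, `helix`,
#'   `position`, `label`, with the anchor table stored as an attribute.
#' @export
assign_bw_numbers <- function(sequence, anchors, ranges = NULL) {
  if (is_helix(sequence)) {
    seq3 <- unname(helix_sequence(sequence))
    idx <- sort(unique(sequence$residue_index))
  } else {
    seq3 <- as_seq3(sequence)
    idx <- seq_along(seq3)
  }
  hx <- as.integer(names(anchors))
  if (anyNA(hx)) abort("anchors must be named by helix number")
  if (anyDuplicated(hx)) {
    abort(sprintf("two anchors supplied for helix %d",
                  hx[anyDuplicated(hx)]))
  }
  pos <- as.integer(unlist(anchors))
  if (any(pos < min(idx)) || any(pos > max(idx))) {
    abort("anchor index outside sequence bounds")
  }
  ord <- order(pos)
  hx <- hx[ord]; pos <- pos[ord]
  if (is.null(ranges)) {
    starts <- c(min(idx), floor((pos[-1] + pos[-length(pos)]) / 2) + 1)
    ends <- c(starts[-1] - 1, max(idx))
    ranges <- tibble::tibble(helix = hx, start = starts, end = ends)
  }
  entries <- purrr::map_dfr(seq_along(hx), function(k) {
    r <- ranges[ranges$helix == hx[k], ]
    if (nrow(r) != 1) abort(sprintf("no range for helix %d", hx[k]))
    ri <- idx[idx >= r$start & idx <= r$end]
    tibble::tibble(residue_index = ri,
                   residue_name = seq3[match(ri, idx)],
                   helix = hx[k],
                   position = 50L + ri - pos[k])
  })
  entries$label <- sprintf("%d.%02d", entries$helix, entries$position)
  out <- entries[order(entries$residue_index), ]
  class(out) <- c("bw_map", class(tibble::tibble()))
  attr(out, "anchors") <- setNames(pos, hx)
  attr(out, "sequence") <- setNames(seq3, idx)
  out
}

#' Look up Ballesteros-Weinstein labels and indices
#'
#' `bw_label()` maps absolute residue indices to labels (loop residues, which
#' sit in no helix, come back as absolute numbers in parentheses, e.g.
#' `"R(220)"`); `bw_index()` inverts a `helix.NN` label to the absolute index.
#'
#' @param map a `bw_map` from [assign_bw_numbers()].
#' @param residue_index integer vector of absolute residue indices.
#' @param label character vector of `helix.NN` labels.
#' @param with_residue prefix helix labels with the one-letter residue code
#'   (`"E1.49"` style) when the sequence is known.
#' @return `bw_label()` a character vector; `bw_index()` an integer vector
#'   (`NA` for labels absent from the map).
#' @export
bw_label <- function(map, residue_index, with_residue = FALSE) {
  seqs <- attr(map, "sequence")
  one_letter <- function(i) {
    rn <- seqs[[as.character(i)]]
    if (!is.null(rn) && rn %in% AA3) AA1[match(rn, AA3)] else ""
  }
  vapply(residue_index, function(i) {
    j <- match(i, map$residue_index)
    if (!is.na(j)) {
      return(if (with_residue) paste0(one_letter(i), map$label[j])
             else map$label[j])
    }
    sprintf("%s(%d)", one_letter(i), i)  # loop residue: absolute number
  }, character(1))
}

#' @rdname bw_label
#' @export
bw_index <- function(map, label) {
  map$residue_index[match(label, map$label)]
}

#' Serialize a Ballesteros-Weinstein map as TSV
#'
#' Two columns: `absolute_index`, `bw_label`.
#' @param map a `bw_map`.
#' @param path output TSV path.
#' @param anchors for `read_bw_map()`: optional anchors to restore attributes.
#' @return `write_bw_map()` returns `path` invisibly; `read_bw_map()` a
#'   `bw_map` tibble.
#' @export
write_bw_map <- function(map, path) {
  utils::write.table(
    data.frame(absolute_index = map$residue_index, bw_label = map$label),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_bw_map
#' @export
read_bw_map <- function(path, anchors = NULL) {
  d <- utils::read.delim(path, stringsAsFactors = FALSE,
                         colClasses = c("integer", "character"))
  parts <- strsplit(d$bw_label, ".", fixed = TRUE)
  out <- tibble::tibble(
    residue_index = as.integer(d$absolute_index),
    residue_name = NA_character_,
    helix = as.integer(vapply(parts, `[`, "", 1)),
    position = as.integer(vapply(parts, `[`, "", 2)),
    label = d$bw_label)
  class(out) <- c("bw_map", class(tibble::tibble()))
  attr(out, "anchors") <- anchors
  out
}
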