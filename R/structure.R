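## Structure data model: a `structure3d` holds one or more `protomer`s
## (chains), each protomer an atom table. Coordinate parsing and writing is
## delegated to bio3d; this layer applies the altloc/model policy, element
## resolution, radius assignment and invariant checks.

## Bondi van der Waals radii (Angstrom) for the elements the default
## pipeline accepts. Selenium and other exotic elements are deliberately
## absent: an explicit radius-table override is required to admit them.
.bondi_default <- c(C = 1.70, N = 1.55, O = 1.52, S = 1.80, P = 1.80,
                    F = 1.47, CL = 1.75, BR = 1.85, I = 1.98,
                    ZN = 1.39, CU = 1.40, H = 1.20)

#' Default van der Waals radius table
#'
#' Bondi radii for the elements handled by default (C, N, O, S, P, halogens,
#' Zn, Cu, H). Override entries or add elements by passing a modified copy to
#' \code{\link{assign_vdw_radii}} or by loading a table with
#' \code{\link{read_radius_table}}.
#'
#' @return Named numeric vector, element symbol (upper case) to radius in
#'   Angstrom.
#' @export
default_radius_table <- function() .bondi_default

#' Read a radius table from a key/value config file
#'
#' Two-column delimited text (element, radius in Angstrom), '#' comments
#' allowed.
#'
#' @param path file path.
#' @return Named numeric vector usable as a radius table.
#' @export
read_radius_table <- function(path) {
  df <- utils::read.table(path, header = FALSE, comment.char = "#",
                          col.names = c("element", "radius"),
                          stringsAsFactors = FALSE)
  r <- as.numeric(df$radius)
  if (any(!is.finite(r) | r <= 0)) stop("radii must be positive numbers",
                                        call. = FALSE)
  stats::setNames(r, toupper(df$element))
}

## Elements whose PDB atom names are the element itself (metals, ions).
.monatomic_names <- c("ZN", "CU", "FE", "MG", "MN", "CA", "NA", "K", "CL",
                      "BR", "I", "CD", "NI", "CO", "HG")

.guess_element <- function(name, hetatm = FALSE) {
  nm <- toupper(trimws(name))
  if (hetatm && nm %in% .monatomic_names) return(nm)
  letters_only <- gsub("[^A-Z]", "", nm)
  if (nchar(letters_only) == 0) return(NA_character_)
  if (substr(letters_only, 1, 2) %in% c("SE", "FE", "ZN", "CU", "MG", "MN") &&
      hetatm) {
    return(substr(letters_only, 1, 2))
  }
  substr(letters_only, 1, 1)
}

.new_protomer <- function(chain_id, atoms, source = "") {
  ord <- order(atoms$resno)
  ## strictly increasing residue numbers (atoms grouped by residue)
  rn <- unique(atoms$resno[ord])
  atoms <- atoms[ord, , drop = FALSE]
  rownames(atoms) <- NULL
  structure(list(chain_id = chain_id, atoms = atoms, source = source),
            class = "protomer")
}

#' Parse a structure from PDB or mmCIF content
#'
#' Reads ATOM/HETATM records of the first model, applying the single-
#' conformer policy: alternate locations other than 'A'/blank are dropped
#' (with a message giving the count). Every atom is assigned an element;
#' heavy atoms receive a van der Waals radius from \code{radius_table}.
#' Author residue numbering is preserved verbatim.
#'
#' @param input path to a coordinate file, or a character vector of file
#'   content lines (PDB format only for literal content).
#' @param format "pdb" or "cif"; default guesses from the file extension
#'   (falling back to "pdb").
#' @param radius_table named element-to-Angstrom vector; see
#'   \code{\link{default_radius_table}}.
#' @param accession free-text accession recorded on the structure; defaults
#'   to the file name.
#' @return A \code{structure3d} object: list with \code{accession},
#'   \code{protomers} (named list of \code{protomer}), \code{resolution}
#'   (NA if unstated) and \code{n_altloc_discarded}.
#' @examples
#' pdb <- make_mini_hairpin()
#' f <- tempfile(fileext = ".pdb")
#' write_structure(pdb, f)
#' s <- parse_structure(f)
#' length(s$protomers)
#' @export
parse_structure <- function(input, format = NULL,
                            radius_table = default_radius_table(),
                            accession = NULL) {
  from_file <- length(input) == 1 && !grepl("\n", input) && file.exists(input)
  if (is.null(format)) {
    format <- if (from_file && grepl("\\.cif$", input, ignore.case = TRUE))
      "cif" else "pdb"
  }
  format <- match.arg(format, c("pdb", "cif"))
  if (!from_file) {
    lines <- unlist(strsplit(input, "\n", fixed = TRUE))
    if (format != "pdb") stop("literal content is supported for PDB only",
                              call. = FALSE)
    path <- tempfile(fileext = ".pdb")
    writeLines(lines, path)
    on.exit(unlink(path))
    if (is.null(accession)) accession <- "inline"
  } else {
    path <- input
    if (is.null(accession))
      accession <- sub("\\.(pdb|cif|ent)$", "", basename(path),
                       ignore.case = TRUE)
  }

  if (format == "pdb") .validate_pdb_records(readLines(path, warn = FALSE))

  at <- if (format == "pdb") {
    suppressWarnings(bio3d::read.pdb(path, multi = FALSE, rm.alt = FALSE,
                                     verbose = FALSE))$atom
  } else {
    ## bio3d's read.cif is beta and rejects many writers' files; fall back
    ## to a direct _atom_site loop read when it fails
    cif <- tryCatch(
      suppressWarnings(bio3d::read.cif(path, multi = FALSE, rm.alt = FALSE,
                                       verbose = FALSE))$atom,
      error = function(e) NULL)
    if (is.null(cif)) .read_cif_atom_site(path) else cif
  }

  alt <- at$alt
  alt[is.na(alt)] <- ""
  keep <- alt %in% c("", "A")
  n_discard <- sum(!keep)
  if (n_discard > 0) {
    message(sprintf("discarded %d alternate-location atom(s) (altloc not 'A')",
                    n_discard))
    at <- at[keep, , drop = FALSE]
  }

  elem <- toupper(trimws(at$elesy))
  miss <- is.na(elem) | elem == ""
  if (any(miss)) {
    elem[miss] <- vapply(seq_len(sum(miss)), function(i) {
      j <- which(miss)[i]
      .guess_element(at$elety[j], hetatm = at$type[j] == "HETATM")
    }, character(1))
  }
  bad <- is.na(elem) | elem == ""
  if (any(bad)) {
    stop("unknown element for atom(s): ",
         paste(unique(at$elety[bad]), collapse = ", "), call. = FALSE)
  }

  atoms <- data.frame(
    name = trimws(at$elety),
    element = elem,
    x = at$x, y = at$y, z = at$z,
    altloc = ifelse(is.na(at$alt) | at$alt == "", "", at$alt),
    occupancy = ifelse(is.na(at$o), 1, at$o),
    resno = at$resno,
    resid = toupper(at$resid),
    chain = ifelse(is.na(at$chain), "A", at$chain),
    insert = ifelse(is.na(at$insert), "", at$insert),
    hetatm = at$type == "HETATM",
    stringsAsFactors = FALSE
  )
  if (any(!is.finite(atoms$x) | !is.finite(atoms$y) | !is.finite(atoms$z))) {
    stop("non-finite coordinates in input", call. = FALSE)
  }

  ## invariant: at most one atom per (residue, name, altloc)
  key <- paste(atoms$chain, atoms$resno, atoms$insert, atoms$name,
               atoms$altloc, sep = "|")
  if (anyDuplicated(key)) {
    dup <- key[duplicated(key)][1]
    stop("duplicate atom (name, altloc) within a residue: ", dup,
         call. = FALSE)
  }

  atoms$is_hydrogen <- atoms$element %in% c("H", "D")
  atoms$vdw <- NA_real_

  chains <- unique(atoms$chain)
  protomers <- lapply(chains, function(ch) {
    .new_protomer(ch, atoms[atoms$chain == ch, , drop = FALSE],
                  source = paste0(accession, ":model1:", ch))
  })
  names(protomers) <- chains

  res <- NA_real_
  if (format == "pdb") {
    hdr <- grep("^REMARK   2 RESOLUTION", readLines(path, warn = FALSE),
                value = TRUE)
    if (length(hdr)) {
      m <- regmatches(hdr[1], regexpr("[0-9]+\\.[0-9]+", hdr[1]))
      if (length(m)) res <- as.numeric(m)
    }
  }

  s <- structure(list(accession = accession, protomers = protomers,
                      resolution = res, n_altloc_discarded = n_discard),
                 class = "structure3d")
  assign_vdw_radii(s, radius_table)
}

## Minimal mmCIF _atom_site loop reader producing a bio3d-shaped atom
## table (first model only). Values are whitespace-delimited; quoted
## tokens are not split.
.read_cif_atom_site <- function(path) {
  lines <- readLines(path, warn = FALSE)
  hdr_idx <- grep("^_atom_site\\.", lines)
  if (!length(hdr_idx)) stop("no _atom_site loop found in mmCIF input",
                             call. = FALSE)
  fields <- sub("^_atom_site\\.", "", trimws(lines[hdr_idx]))
  body_start <- max(hdr_idx) + 1
  rows <- list()
  tokenize <- function(ln) {
    # split on whitespace, keeping '...'/"..." tokens intact
    m <- gregexpr("'[^']*'|\"[^\"]*\"|\\S+", ln)[[1]]
    toks <- regmatches(ln, list(m))[[1]]
    gsub("^['\"]|['\"]$", "", toks)
  }
  for (i in body_start:length(lines)) {
    ln <- trimws(lines[i])
    if (ln == "" || startsWith(ln, "#") || startsWith(ln, "_") ||
        startsWith(ln, "loop_") || startsWith(ln, "data_")) break
    toks <- tokenize(ln)
    if (length(toks) != length(fields)) {
      stop(sprintf("malformed _atom_site record at line %d", i),
           call. = FALSE)
    }
    rows[[length(rows) + 1]] <- toks
  }
  if (!length(rows)) stop("empty _atom_site loop", call. = FALSE)
  m <- do.call(rbind, rows)
  colnames(m) <- fields
  g <- function(nm, alt = NULL, default = NA) {
    if (nm %in% fields) m[, nm]
    else if (!is.null(alt) && alt %in% fields) m[, alt]
    else rep(default, nrow(m))
  }
  mdl <- g("pdbx_PDB_model_num", default = "1")
  keep <- mdl == mdl[1]
  clean <- function(x) ifelse(x %in% c(".", "?"), NA, x)
  data.frame(
    type = g("group_PDB", default = "ATOM")[keep],
    elety = clean(g("auth_atom_id", "label_atom_id"))[keep],
    alt = clean(g("label_alt_id"))[keep],
    resid = clean(g("auth_comp_id", "label_comp_id"))[keep],
    chain = clean(g("auth_asym_id", "label_asym_id"))[keep],
    resno = as.integer(clean(g("auth_seq_id", "label_seq_id"))[keep]),
    insert = clean(g("pdbx_PDB_ins_code"))[keep],
    x = as.numeric(g("Cartn_x")[keep]),
    y = as.numeric(g("Cartn_y")[keep]),
    z = as.numeric(g("Cartn_z")[keep]),
    o = as.numeric(clean(g("occupancy", default = "1"))[keep]),
    b = as.numeric(clean(g("B_iso_or_equiv", default = "0"))[keep]),
    elesy = clean(g("type_symbol"))[keep],
    stringsAsFactors = FALSE)
}

.validate_pdb_records <- function(lines) {
  rec <- grepl("^(ATOM  |HETATM)", lines)
  if (!any(rec)) stop("no ATOM/HETATM records found", call. = FALSE)
  ## first model only: truncate at the first ENDMDL
  endm <- grep("^ENDMDL", lines)
  idx <- which(rec)
  if (length(endm)) idx <- idx[idx < endm[1]]
  for (i in idx) {
    ln <- lines[i]
    if (nchar(ln) < 54) {
      stop(sprintf("malformed ATOM record at line %d: too short", i),
           call. = FALSE)
    }
    coords <- c(substr(ln, 31, 38), substr(ln, 39, 46), substr(ln, 47, 54))
    if (any(is.na(suppressWarnings(as.numeric(coords))))) {
      stop(sprintf("malformed ATOM record at line %d: non-numeric coordinates",
                   i), call. = FALSE)
    }
  }
  invisible(TRUE)
}

#' Assign van der Waals radii from an element table
#'
#' Every heavy atom receives the radius for its element; hydrogens are
#' flagged and left radius-less (they are excluded from default contact
#' analysis). Atom count is conserved.
#'
#' @param structure a \code{structure3d}.
#' @param radius_table named element-to-Angstrom vector.
#' @return The structure with radii filled in.
#' @export
assign_vdw_radii <- function(structure, radius_table = default_radius_table()) {
  stopifnot(inherits(structure, "structure3d"))
  names(radius_table) <- toupper(names(radius_table))
  structure$protomers <- lapply(structure$protomers, function(p) {
    heavy <- !p$atoms$is_hydrogen
    el <- toupper(p$atoms$element[heavy])
    missing_el <- setdiff(unique(el), names(radius_table))
    if (length(missing_el)) {
      stop("radius table does not cover element(s): ",
           paste(missing_el, collapse = ", "), call. = FALSE)
    }
    p$atoms$vdw[heavy] <- unname(radius_table[el])
    p
  })
  structure
}

#' Write a structure to a PDB file
#'
#' @param structure a \code{structure3d}.
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @export
write_structure <- function(structure, path) {
  stopifnot(inherits(structure, "structure3d"))
  at <- do.call(rbind, lapply(structure$protomers, `[[`, "atoms"))
  bio3d::write.pdb(
    file = path,
    xyz = as.numeric(t(as.matrix(at[, c("x", "y", "z")]))),
    resno = at$resno,
    resid = at$resid,
    eleno = seq_len(nrow(at)),
    elety = at$name,
    chain = at$chain,
    insert = ifelse(at$insert == "", NA, at$insert),
    alt = ifelse(at$altloc == "", NA, at$altloc),
    o = at$occupancy,
    b = rep(0, nrow(at)),
    elesy = at$element,
    type = ifelse(at$hetatm, "HETATM", "ATOM")
  )
  invisible(path)
}

#' Extract one residue from a protomer
#'
#' @param protomer a \code{protomer}.
#' @param resno author residue number.
#' @return A \code{residue}: list with \code{number}, \code{amino_acid}
#'   (3-letter code), \code{atoms} (atom table), \code{incomplete} (TRUE when
#'   a backbone atom is missing).
#' @export
get_residue <- function(protomer, resno) {
  stopifnot(inherits(protomer, "protomer"))
  sel <- protomer$atoms$resno == resno & !protomer$atoms$hetatm
  if (!any(sel)) {
    sel <- protomer$atoms$resno == resno
    if (!any(sel)) stop("no residue numbered ", resno, " in chain ",
                        protomer$chain_id, call. = FALSE)
  }
  at <- protomer$atoms[sel, , drop = FALSE]
  aa <- at$resid[1]
  bb <- c("N", "CA", "C", "O")
  structure(list(number = resno, amino_acid = aa, atoms = at,
                 incomplete = !all(bb %in% at$name)),
            class = "residue")
}

#' Coordinates of named atoms in a residue
#'
#' @param residue a \code{residue}.
#' @param names atom names; default the backbone N, CA, C, O.
#' @param strict error when an atom is absent (default) or drop it.
#' @return Matrix with one row per found atom, rownames the atom names.
#' @export
residue_coords <- function(residue, names = c("N", "CA", "C", "O"),
                           strict = TRUE) {
  at <- residue$atoms
  idx <- match(names, at$name)
  if (strict && anyNA(idx)) {
    stop("residue ", residue$number, " (", residue$amino_acid,
         ") lacks atom(s): ", paste(names[is.na(idx)], collapse = ", "),
         call. = FALSE)
  }
  idx <- idx[!is.na(idx)]
  m <- as.matrix(at[idx, c("x", "y", "z")])
  rownames(m) <- at$name[idx]
  m
}

#' Residue numbers present in a protomer
#' @param protomer a \code{protomer}.
#' @param polymer_only drop HETATM-only residues (default TRUE).
#' @return Integer vector of author residue numbers, in order.
#' @export
residue_numbers <- function(protomer, polymer_only = TRUE) {
  at <- protomer$atoms
  if (polymer_only) at <- at[!at$hetatm, , drop = FALSE]
  unique(at$resno)
}

#' Build a structure3d from a list of protomers
#' @param protomers list of \code{protomer} objects.
#' @param accession free-text accession.
#' @param resolution resolution in Angstrom, or NA.
#' @return A \code{structure3d}.
#' @export
as_structure3d <- function(protomers, accession = "synthetic",
                           resolution = NA_real_) {
  if (inherits(protomers, "protomer")) protomers <- list(protomers)
  stopifnot(length(protomers) >= 1,
            all(vapply(protomers, inherits, logical(1), "protomer")))
  nm <- vapply(protomers, `[[`, character(1), "chain_id")
  names(protomers) <- make.unique(nm)
  structure(list(accession = accession, protomers = protomers,
                 resolution = resolution, n_altloc_discarded = 0L),
            class = "structure3d")
}

#' @export
print.structure3d <- function(x, ...) {
  cat("<structure3d>", x$accession,
      if (is.finite(x$resolution)) sprintf("(%.2f A)", x$resolution) else "",
      "\n")
  for (p in x$protomers) {
    nres <- length(residue_numbers(p))
    cat(sprintf("  chain %s: %d residues, %d atoms\n",
                p$chain_id, nres, nrow(p$atoms)))
  }
  invisible(x)
}

#' @export
print.protomer <- function(x, ...) {
  cat(sprintf("<protomer> chain %s: %d residues, %d atoms (%s)\n",
              x$chain_id, length(residue_numbers(x)), nrow(x$atoms),
              x$source))
  invisible(x)
}

#' @export
print.residue <- function(x, ...) {
  cat(sprintf("<residue> %s%d: %d atoms%s\n", x$amino_acid, x$number,
              nrow(x$atoms), if (x$incomplete) " (incomplete backbone)" else ""))
  invisible(x)
}
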