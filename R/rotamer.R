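## Rotamer engine: measure chi dihedrals, enumerate candidate rotamers
## (compact canonical library, chi grid, optional coarse backbone-dependent
## filtering) and rebuild side chains from ideal internal coordinates on a
## fixed backbone.

#' Chi angles of a residue conformation
#'
#' @param values numeric vector of dihedrals, degrees in (-180, 180].
#' @param amino_acid 3-letter code; length of \code{values} must equal its
#'   canonical chi count.
#' @return A \code{chi_angles} object.
#' @export
chi_angles <- function(values, amino_acid) {
  aa <- aa_three(amino_acid)
  values <- as.numeric(values)
  if (length(values) != chi_count(aa)) {
    stop(sprintf("%s has %d chi angle(s), got %d", aa, chi_count(aa),
                 length(values)), call. = FALSE)
  }
  values <- ((values + 180) %% 360) - 180
  values[values == -180] <- 180
  structure(list(values = values, amino_acid = aa), class = "chi_angles")
}

#' @export
print.chi_angles <- function(x, ...) {
  cat(sprintf("<chi_angles> %s: %s\n", x$amino_acid,
              if (length(x$values)) paste(sprintf("%.1f", x$values),
                                          collapse = ", ") else "(none)"))
  invisible(x)
}

#' Measure the chi dihedrals of a residue
#'
#' Applies the standard four-atom chi definitions for the residue's amino
#' acid. Gly and Ala give an empty result.
#'
#' @param residue a \code{residue} (see \code{\link{get_residue}}), or an
#'   atom-name-rowed coordinate matrix.
#' @return A \code{chi_angles} object.
#' @export
measure_chi <- function(residue) {
  aa <- residue$amino_acid
  defs <- .chi_defs(aa)
  if (!length(defs)) return(chi_angles(numeric(0), aa))
  vals <- vapply(seq_along(defs), function(k) {
    nm <- defs[[k]]
    m <- tryCatch(residue_coords(residue, nm),
                  error = function(e) {
                    stop(sprintf("chi%d of %s%s undefined: %s", k, aa,
                                 if (!is.null(residue$number))
                                   residue$number else "",
                                 conditionMessage(e)), call. = FALSE)
                  })
    dihedral_angle(m[1, ], m[2, ], m[3, ], m[4, ])
  }, numeric(1))
  chi_angles(vals, aa)
}

## ---- Rotamer library ---------------------------------------------------

#' A single rotamer
#'
#' @param amino_acid 3-letter code.
#' @param chi numeric chi vector (length must match the amino acid).
#' @param source "library" or "grid".
#' @param label short free-text label (e.g., "mt0").
#' @return A \code{rotamer} object.
#' @export
rotamer <- function(amino_acid, chi, source = "library", label = "") {
  ca <- chi_angles(chi, amino_acid)
  structure(list(amino_acid = ca$amino_acid, chi = ca$values,
                 source = source, label = label), class = "rotamer")
}

#' @export
print.rotamer <- function(x, ...) {
  cat(sprintf("<rotamer> %s %s [%s]: %s\n", x$amino_acid, x$label, x$source,
              if (length(x$chi)) paste(sprintf("%.0f", x$chi),
                                       collapse = ", ") else "(no chi)"))
  invisible(x)
}

#' Load the packaged canonical rotamer library
#'
#' A compact backbone-independent library built from staggered sp3 wells
#' (-60/60/180), a reduced set for near-symmetric terminal carboxylates
#' (0/90), and coarse samples for terminal amides, aromatic and guanidinium
#' torsions. Gly and Ala map to the single trivial rotamer.
#'
#' @param path optional path to an alternative library CSV (columns
#'   amino_acid, label, chi1..chi4; empty cells for unused chi).
#' @return A \code{rotamer_library}: list with \code{entries} (amino acid ->
#'   list of \code{rotamer}) and \code{backbone_dependent = FALSE}.
#' @export
default_rotamer_library <- function(path = NULL) {
  if (is.null(path)) {
    cached <- get0(".rotlib_cache", envir = .steriscan_env)
    if (!is.null(cached)) return(cached)
    path <- system.file("extdata", "rotamer_library.csv",
                        package = "steriscan", mustWork = TRUE)
  }
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  entries <- lapply(split(df, df$amino_acid), function(d) {
    lapply(seq_len(nrow(d)), function(i) {
      chi <- as.numeric(d[i, paste0("chi", seq_len(4))])
      chi <- chi[!is.na(chi)]
      rotamer(d$amino_acid[i], chi, source = "library", label = d$label[i])
    })
  })
  for (aa in c("GLY", "ALA")) {
    if (is.null(entries[[aa]])) {
      entries[[aa]] <- list(rotamer(aa, numeric(0), "library", "trivial"))
    }
  }
  lib <- structure(list(entries = entries, backbone_dependent = FALSE,
                        phi_psi_bins = NULL), class = "rotamer_library")
  assign(".rotlib_cache", lib, envir = .steriscan_env)
  lib
}

.steriscan_env <- new.env(parent = emptyenv())

#' Enumerate candidate rotamers for an amino acid
#'
#' Library mode returns the library's entry list; grid mode returns the
#' Cartesian product of a chi grid (default 30 degree steps for chi1/chi2,
#' 60 beyond, a uniform step when \code{grid_step} is scalar). When
#' \code{backbone_dependent = TRUE} the list is filtered to the chi1 wells
#' allowed in the coarse phi/psi bin (see
#' \code{\link{filter_rotamers_backbone}}); this requires \code{phi_psi}.
#'
#' @param amino_acid 3-letter code.
#' @param library a \code{rotamer_library}; used in library mode.
#' @param mode "library" or "grid".
#' @param grid_step degrees; scalar or per-chi vector, recycled.
#' @param backbone_dependent filter by backbone bin?
#' @param phi_psi length-2 numeric (phi, psi) in degrees, required when
#'   \code{backbone_dependent}.
#' @return List of \code{rotamer} objects (a single trivial rotamer for
#'   Gly/Ala).
#' @examples
#' length(enumerate_rotamers("VAL"))                   # 3
#' length(enumerate_rotamers("GLU", mode = "grid", grid_step = 60))  # 216
#' @export
enumerate_rotamers <- function(amino_acid,
                               library = default_rotamer_library(),
                               mode = c("library", "grid"),
                               grid_step = c(30, 30, 60, 60),
                               backbone_dependent = FALSE,
                               phi_psi = NULL) {
  aa <- aa_three(amino_acid)
  mode <- match.arg(mode)
  nchi <- chi_count(aa)
  if (nchi == 0) return(list(rotamer(aa, numeric(0), mode, "trivial")))
  rots <- if (mode == "library") {
    ent <- library$entries[[aa]]
    if (is.null(ent) || !length(ent)) {
      stop("rotamer library has no entries for ", aa, call. = FALSE)
    }
    ent
  } else {
    step <- rep_len(grid_step, nchi)
    grids <- lapply(step, function(s) seq(-180 + s, 180, by = s))
    combos <- expand.grid(grids, KEEP.OUT.ATTRS = FALSE)
    lapply(seq_len(nrow(combos)), function(i) {
      chi <- as.numeric(combos[i, ])
      rotamer(aa, chi, "grid", paste0("g", i))
    })
  }
  if (backbone_dependent) {
    if (is.null(phi_psi)) {
      stop("backbone-dependent enumeration requires phi_psi", call. = FALSE)
    }
    rots <- filter_rotamers_backbone(rots, phi_psi[1], phi_psi[2])
  }
  rots
}

#' Coarse backbone-dependent rotamer filter
#'
#' Maps phi/psi (on 20-degree bins) to allowed chi1 wells: in the broad
#' alpha and beta regions the g+ well (chi1 near +60) is excluded, the
#' standard coarse reading of backbone dependence; elsewhere all wells are
#' allowed. Rotamers whose chi1 lies in a disallowed well are dropped; the
#' full list is returned if filtering would empty it.
#'
#' @param rotamers list of \code{rotamer}.
#' @param phi,psi backbone dihedrals, degrees.
#' @return Filtered rotamer list.
#' @export
filter_rotamers_backbone <- function(rotamers, phi, psi) {
  if (!length(rotamers) || !length(rotamers[[1]]$chi)) return(rotamers)
  bin <- function(x) 20 * floor(x / 20)
  phi <- bin(phi); psi <- bin(psi)
  in_beta  <- phi <= -60 && (psi >= 80 || psi <= -160)
  in_alpha <- phi <= -20 && phi >= -160 && psi >= -120 && psi < 60
  if (!(in_beta || in_alpha)) return(rotamers)
  well <- function(chi1) {
    if (chi1 > 0 && chi1 <= 120) "p" else if (chi1 > -120 && chi1 <= 0) "m"
    else "t"
  }
  keep <- vapply(rotamers, function(r) well(r$chi[1]) != "p", logical(1))
  if (!any(keep)) return(rotamers)
  rotamers[keep]
}

## ---- Side-chain construction ------------------------------------------

.element_from_name <- function(name) substr(gsub("[^A-Z]", "", name), 1, 1)

#' Build side-chain heavy atoms on a fixed backbone
#'
#' Places CB from N/CA/C by ideal tetrahedral geometry (L-chirality), then
#' each further heavy atom by successive internal-coordinate construction
#' with the chi torsions taken from \code{rotamer}. Measuring chi on the
#' result returns the rotamer's values (to well below 1e-6 degrees).
#'
#' @param backbone a \code{residue} with N, CA, C (and O) present, or a
#'   coordinate matrix with rows named N, CA, C.
#' @param target 3-letter code of the amino acid to build.
#' @param rotamer a \code{rotamer} for \code{target}.
#' @param geometry ideal-geometry table, default
#'   \code{\link{sidechain_geometry}(target)}.
#' @return Data frame of placed atoms: name, element, x, y, z (Gly: zero
#'   rows; Ala: CB only).
#' @export
build_side_chain <- function(backbone, target, rotamer = NULL,
                             geometry = NULL) {
  aa <- aa_three(target)
  if (is.null(rotamer)) rotamer <- rotamer(aa, rep(180, chi_count(aa)))
  if (rotamer$amino_acid != aa) {
    stop("rotamer is for ", rotamer$amino_acid, ", not ", aa, call. = FALSE)
  }
  coords <- if (inherits(backbone, "residue")) {
    residue_coords(backbone, c("N", "CA", "C"))
  } else {
    as.matrix(backbone)[c("N", "CA", "C"), , drop = FALSE]
  }
  pos <- list(N = coords["N", ], CA = coords["CA", ], C = coords["C", ])

  empty <- data.frame(name = character(0), element = character(0),
                      x = numeric(0), y = numeric(0), z = numeric(0),
                      stringsAsFactors = FALSE)
  if (aa == "GLY") return(empty)

  if (aa != "ALA" && is.null(geometry)) geometry <- sidechain_geometry(aa)
  rows <- rbind(.cb_row, if (aa != "ALA") geometry)
  out <- empty
  for (i in seq_len(nrow(rows))) {
    r <- rows[i, ]
    tor <- if (is.na(r$chi)) r$offset else rotamer$chi[r$chi] + r$offset
    for (ref in c(r$a, r$b, r$c)) {
      if (is.null(pos[[ref]])) stop("missing reference atom ", ref,
                                    call. = FALSE)
    }
    p <- place_atom(pos[[r$a]], pos[[r$b]], pos[[r$c]], r$bond, r$angle, tor)
    pos[[r$atom]] <- p
    out <- rbind(out, data.frame(name = r$atom,
                                 element = .element_from_name(r$atom),
                                 x = p[1], y = p[2], z = p[3],
                                 stringsAsFactors = FALSE))
  }
  rownames(out) <- NULL
  out
}

## ---- Variant specification and residue replacement ---------------------

#' Specify a point substitution or deletion
#'
#' @param position author residue number.
#' @param wild_type 1- or 3-letter code expected at the position (checked
#'   against the template at scan time).
#' @param substitution 1- or 3-letter code, or "DEL" for an in-frame
#'   deletion.
#' @return A \code{variant_spec} object.
#' @export
variant_spec <- function(position, wild_type, substitution) {
  sub <- toupper(substitution)
  if (sub %in% c("DEL", "DELETION")) sub <- "DEL" else sub <- aa_three(sub)
  structure(list(position = as.integer(position),
                 wild_type = aa_three(wild_type),
                 substitution = sub),
            class = "variant_spec")
}

#' Parse a variant string such as "E40G" or "E133del"
#' @param x character vector, wild-type letter + position + substitution
#'   letter (or "del"/"Del").
#' @return A \code{variant_spec} (or list of them when length(x) > 1).
#' @export
parse_variant <- function(x) {
  one <- function(s) {
    m <- regmatches(s, regexec("^([A-Za-z])([0-9]+)(del|Del|DEL|[A-Za-z])$",
                               s))[[1]]
    if (length(m) != 4) stop("cannot parse variant '", s, "'", call. = FALSE)
    sub <- if (toupper(m[4]) == "DEL") "DEL" else m[4]
    variant_spec(as.integer(m[3]), m[2], sub)
  }
  if (length(x) == 1) one(x) else lapply(x, one)
}

#' @export
print.variant_spec <- function(x, ...) {
  cat(sprintf("<variant> %s%d -> %s\n", x$wild_type, x$position,
              x$substitution))
  invisible(x)
}

#' @export
format.variant_spec <- function(x, ...) {
  sub1 <- if (x$substitution == "DEL") "del"
          else names(.aa1to3)[match(x$substitution, .aa1to3)]
  wt1 <- names(.aa1to3)[match(x$wild_type, .aa1to3)]
  paste0(wt1, x$position, sub1)
}

#' Replace one residue's side chain in a protomer
#'
#' The target residue's side chain is rebuilt as the substituted amino acid
#' at the given rotamer; the backbone (N, CA, C, O, OXT) is untouched and
#' every other residue is copied verbatim. Deletions are refused here: they
#' are handled by the rule-based path of \code{\link{classify_variant}}.
#'
#' @param protomer a \code{protomer}.
#' @param variant a \code{variant_spec} (substitution, not DEL).
#' @param rotamer a \code{rotamer} for the substituted amino acid.
#' @param radius_table for radius assignment on the new atoms.
#' @return The mutated \code{protomer}.
#' @export
replace_residue <- function(protomer, variant, rotamer,
                            radius_table = default_radius_table()) {
  stopifnot(inherits(protomer, "protomer"),
            inherits(variant, "variant_spec"))
  if (variant$substitution == "DEL") {
    stop("deletions are not modeled geometrically; classify_variant ",
         "handles them by the register-shift rule", call. = FALSE)
  }
  res <- get_residue(protomer, variant$position)
  if (res$amino_acid != variant$wild_type) {
    stop(sprintf("template residue %d is %s, not the expected %s",
                 variant$position, res$amino_acid, variant$wild_type),
         call. = FALSE)
  }
  side <- build_side_chain(res, variant$substitution, rotamer)

  at <- protomer$atoms
  in_res <- at$resno == variant$position & !at$hetatm
  bb_keep <- in_res & at$name %in% c("N", "CA", "C", "O", "OXT")
  keep <- !in_res | bb_keep
  at2 <- at[keep, , drop = FALSE]
  at2$resid[at2$resno == variant$position & !at2$hetatm] <-
    variant$substitution

  if (nrow(side)) {
    tmpl <- at[which(in_res)[1], , drop = FALSE]
    add <- tmpl[rep(1, nrow(side)), , drop = FALSE]
    add$name <- side$name
    add$element <- side$element
    add$x <- side$x; add$y <- side$y; add$z <- side$z
    add$altloc <- ""; add$occupancy <- 1
    add$resid <- variant$substitution
    add$is_hydrogen <- FALSE
    add$vdw <- unname(radius_table[toupper(add$element)])
    if (anyNA(add$vdw)) stop("radius table missing element for built atoms",
                             call. = FALSE)
    ## insert side-chain atoms directly after the residue's backbone
    pos_idx <- which(at2$resno == variant$position & !at2$hetatm)
    after <- max(pos_idx)
    at2 <- rbind(at2[seq_len(after), , drop = FALSE], add,
                 if (after < nrow(at2))
                   at2[(after + 1):nrow(at2), , drop = FALSE])
  }
  rownames(at2) <- NULL
  protomer$atoms <- at2
  protomer
}

## ---- Ideal-geometry peptide builder ------------------------------------

#' Build a peptide with ideal backbone geometry
#'
#' Constructs N/CA/C/O (and side chains) for a sequence at given phi/psi,
#' trans peptide bonds, using standard backbone bond lengths and angles.
#' The first residue's N sits at \code{origin}. Used by the synthetic
#' fixture generators; also handy for building test cases.
#'
#' @param sequence character vector of 1- or 3-letter codes.
#' @param phi,psi backbone dihedrals in degrees, recycled over residues
#'   (phi of the first residue and psi of the last are not realised as
#'   torsions but still orient O placement).
#' @param chi list of per-residue chi vectors (NULL entries get an extended
#'   side chain, all-180 / library-free default).
#' @param chain_id chain identifier.
#' @param start_resno first residue number.
#' @param radius_table for radius assignment.
#' @return A \code{protomer}.
#' @export
build_peptide <- function(sequence, phi = -139, psi = 135, chi = NULL,
                          chain_id = "A", start_resno = 1L,
                          radius_table = default_radius_table()) {
  seq3 <- aa_three(sequence)
  n <- length(seq3)
  phi <- rep_len(phi, n); psi <- rep_len(psi, n)
  if (is.null(chi)) chi <- vector("list", n)

  ## backbone ideal values
  b_NCA <- 1.458; b_CAC <- 1.525; b_CN <- 1.329; b_CO <- 1.231
  a_NCAC <- 111.2; a_CACN <- 116.2; a_CNCA <- 121.7; a_CACO <- 120.8

  Npos <- CApos <- Cpos <- vector("list", n)
  Npos[[1]] <- c(0, 0, 0)
  CApos[[1]] <- c(b_NCA, 0, 0)
  th <- .deg2rad(180 - a_NCAC)
  Cpos[[1]] <- CApos[[1]] + b_CAC * c(cos(th), sin(th), 0)
  for (i in seq_len(n - 1)) {
    Npos[[i + 1]] <- place_atom(Npos[[i]], CApos[[i]], Cpos[[i]],
                                b_CN, a_CACN, psi[i])
    CApos[[i + 1]] <- place_atom(CApos[[i]], Cpos[[i]], Npos[[i + 1]],
                                 b_NCA, a_CNCA, 180)  # trans omega
    Cpos[[i + 1]] <- place_atom(Cpos[[i]], Npos[[i + 1]], CApos[[i + 1]],
                                b_CAC, a_NCAC, phi[i + 1])
  }

  rows <- list()
  for (i in seq_len(n)) {
    O <- place_atom(Npos[[i]], CApos[[i]], Cpos[[i]], b_CO, a_CACO,
                    psi[i] + 180)
    bb <- rbind(N = Npos[[i]], CA = CApos[[i]], C = Cpos[[i]])
    nchi_i <- chi_count(seq3[i])
    rot <- if (nchi_i == 0) rotamer(seq3[i], numeric(0))
           else if (is.null(chi[[i]])) rotamer(seq3[i], rep(180, nchi_i))
           else rotamer(seq3[i], chi[[i]])
    side <- build_side_chain(bb, seq3[i], rot)
    nm <- c("N", "CA", "C", "O", side$name)
    el <- c("N", "C", "C", "O", side$element)
    xyz <- rbind(Npos[[i]], CApos[[i]], Cpos[[i]], O,
                 as.matrix(side[, c("x", "y", "z")]))
    rows[[i]] <- data.frame(
      name = nm, element = el,
      x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
      altloc = "", occupancy = 1,
      resno = start_resno + i - 1L, resid = seq3[i],
      chain = chain_id, insert = "", hetatm = FALSE,
      is_hydrogen = FALSE,
      vdw = unname(radius_table[el]),
      stringsAsFactors = FALSE)
  }
  at <- do.call(rbind, rows)
  rownames(at) <- NULL
  .new_protomer(chain_id, at, source = "built:ideal")
}
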