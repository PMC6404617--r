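## Ensemble operations: superpose protomers onto a reference over a
## backbone selection, and census a donor's hydrogen-bond partner across
## the ensemble (one best partner, or "none", per protomer).

#' Parse an atom selection
#'
#' Syntax \code{"start-end@ATOM,ATOM"} (residue range, atom names) with an
#' optional leading \code{"chain:"} which is recorded but not enforced when
#' protomers are superposed individually. Omitting \code{@...} selects the
#' backbone N, CA, C, O; omitting the range selects all residues.
#'
#' @param x selection string, e.g. \code{"A:3-10@N,CA,C,O"}.
#' @return List with \code{chain}, \code{resno} (integer vector or NULL)
#'   and \code{atoms}.
#' @export
parse_selection <- function(x) {
  chain <- NULL
  if (grepl(":", x, fixed = TRUE)) {
    parts <- strsplit(x, ":", fixed = TRUE)[[1]]
    chain <- parts[1]
    x <- parts[2]
  }
  atoms <- c("N", "CA", "C", "O")
  if (grepl("@", x, fixed = TRUE)) {
    parts <- strsplit(x, "@", fixed = TRUE)[[1]]
    rng <- parts[1]
    if (length(parts) < 2 || !nzchar(trimws(parts[2]))) {
      stop("empty atom selection", call. = FALSE)
    }
    atoms <- trimws(strsplit(parts[2], ",", fixed = TRUE)[[1]])
  } else rng <- x
  resno <- NULL
  if (nzchar(trimws(rng))) {
    m <- regmatches(rng, regexec("^([0-9]+)-([0-9]+)$", trimws(rng)))[[1]]
    if (length(m) == 3) {
      resno <- seq.int(as.integer(m[2]), as.integer(m[3]))
    } else {
      resno <- as.integer(trimws(strsplit(rng, ",", fixed = TRUE)[[1]]))
      if (anyNA(resno)) stop("cannot parse residue range '", rng, "'",
                             call. = FALSE)
    }
  }
  if (!length(atoms) || any(!nzchar(atoms))) {
    stop("empty atom selection", call. = FALSE)
  }
  list(chain = chain, resno = resno, atoms = atoms)
}

.selection_coords <- function(protomer, selection) {
  at <- protomer$atoms[!protomer$atoms$hetatm, , drop = FALSE]
  resno <- selection$resno
  if (is.null(resno)) resno <- unique(at$resno)
  rows <- list()
  for (rn in resno) {
    for (nm in selection$atoms) {
      i <- which(at$resno == rn & at$name == nm)
      if (!length(i)) {
        stop(sprintf("selection atom %s of residue %d missing in protomer %s",
                     nm, rn, protomer$chain_id), call. = FALSE)
      }
      rows[[length(rows) + 1]] <- c(at$x[i[1]], at$y[i[1]], at$z[i[1]])
    }
  }
  if (!length(rows)) stop("empty selection", call. = FALSE)
  do.call(rbind, rows)
}

#' Superpose an ensemble of protomers onto a reference
#'
#' Kabsch-fits every protomer's selected atoms onto the reference
#' protomer's and applies the transform to all of its atoms.
#'
#' @param protomers list of \code{protomer} objects.
#' @param reference_index index of the reference protomer (default 1).
#' @param selection selection string or parsed list (default: backbone
#'   N, CA, C, O of all shared residues); see \code{\link{parse_selection}}.
#' @return List of class \code{ensemble_superposition}: \code{protomers}
#'   (transformed), \code{rmsd} (per protomer, Angstrom),
#'   \code{transforms}, \code{reference_index}, \code{selection}.
#' @export
superpose_ensemble <- function(protomers, reference_index = 1,
                               selection = NULL) {
  stopifnot(length(protomers) >= 1)
  if (is.character(selection)) selection <- parse_selection(selection)
  if (is.null(selection)) {
    selection <- list(chain = NULL, resno = NULL,
                      atoms = c("N", "CA", "C", "O"))
  }
  if (is.null(selection$resno)) {
    shared <- Reduce(intersect, lapply(protomers, residue_numbers))
    selection$resno <- shared
  }
  ref_xyz <- .selection_coords(protomers[[reference_index]], selection)
  out <- protomers
  rmsd <- numeric(length(protomers))
  trs <- vector("list", length(protomers))
  for (i in seq_along(protomers)) {
    mob <- .selection_coords(protomers[[i]], selection)
    if (nrow(mob) != nrow(ref_xyz)) {
      stop("selection size differs between protomer ", i, " and reference",
           call. = FALSE)
    }
    tr <- kabsch_superpose(mob, ref_xyz)
    rmsd[i] <- tr$rmsd
    trs[[i]] <- tr
    at <- out[[i]]$atoms
    xyz <- apply_transform(tr, as.matrix(at[, c("x", "y", "z")]))
    at$x <- xyz[, 1]; at$y <- xyz[, 2]; at$z <- xyz[, 3]
    out[[i]]$atoms <- at
  }
  structure(list(protomers = out, rmsd = rmsd, transforms = trs,
                 reference_index = reference_index, selection = selection),
            class = "ensemble_superposition")
}

#' @export
print.ensemble_superposition <- function(x, ...) {
  cat(sprintf("<ensemble_superposition> %d protomer(s) onto #%d; rmsd %.4f-%.4f A\n",
              length(x$protomers), x$reference_index,
              min(x$rmsd), max(x$rmsd)))
  invisible(x)
}

.parse_atomspec <- function(x) {
  if (is.list(x)) return(x)
  parts <- strsplit(x, ":", fixed = TRUE)[[1]]
  if (length(parts) != 2) stop("atom spec must be 'resno:ATOM[,ATOM]'",
                               call. = FALSE)
  list(resno = as.integer(parts[1]),
       atoms = trimws(strsplit(parts[2], ",", fixed = TRUE)[[1]]))
}

#' Census a donor's hydrogen-bond partner across an ensemble
#'
#' For each protomer, the donor atom is tested against every candidate
#' acceptor group under the geometric criteria; the protomer is assigned
#' the single best-satisfying partner (minimal donor-acceptor distance,
#' ties broken by partner label) or "none". Protomers lacking the donor
#' atom are excluded and reported. Partner counts always sum to the number
#' of included protomers.
#'
#' @param protomers list of \code{protomer} objects (e.g., a superposed
#'   ensemble's \code{$protomers}).
#' @param donor atom spec \code{"resno:ATOM"} (e.g., \code{"91:NZ"}) or an
#'   equivalent list.
#' @param acceptors named list of candidate partner specs, each
#'   \code{"resno:ATOM[,ATOM]"}; the names label the census (e.g.,
#'   \code{list(D92 = "92:OD1,OD2", E40 = "40:OE1,OE2")}).
#' @param criteria an \code{\link{hbond_criteria}}.
#' @return An \code{hbond_census}: \code{donor}, \code{partner_counts}
#'   (named integer vector including "none"), \code{total},
#'   \code{excluded} (indices), \code{assignments} (per-protomer labels).
#' @export
census_hbonds <- function(protomers, donor, acceptors,
                          criteria = hbond_criteria()) {
  dspec <- .parse_atomspec(donor)
  if (length(dspec$atoms) != 1) stop("donor spec must name one atom",
                                     call. = FALSE)
  if (is.null(names(acceptors)) && length(acceptors)) {
    names(acceptors) <- vapply(acceptors, function(a)
      paste0("res", .parse_atomspec(a)$resno), character(1))
  }
  aspecs <- lapply(acceptors, .parse_atomspec)

  labels <- character(0)
  excluded <- integer(0)
  for (i in seq_along(protomers)) {
    at <- protomers[[i]]$atoms
    di <- which(at$resno == dspec$resno & at$name == dspec$atoms &
                  !at$hetatm)
    if (!length(di)) { excluded <- c(excluded, i); next }
    di <- di[1]
    dres <- at$resid[di]
    ante_name <- hbond_donors(dres)[dspec$atoms]
    if (is.na(ante_name)) {
      stop(sprintf("atom %s of %s is not a known donor", dspec$atoms, dres),
           call. = FALSE)
    }
    ai <- which(at$resno == dspec$resno & at$name == ante_name & !at$hetatm)
    if (!length(ai)) { excluded <- c(excluded, i); next }
    d <- c(at$x[di], at$y[di], at$z[di])
    a0 <- c(at$x[ai[1]], at$y[ai[1]], at$z[ai[1]])

    best_label <- "none"; best_dist <- Inf
    for (lab in sort(names(aspecs))) {
      sp <- aspecs[[lab]]
      for (nm in sp$atoms) {
        ci <- which(at$resno == sp$resno & at$name == nm & !at$hetatm)
        if (!length(ci)) next
        a <- c(at$x[ci[1]], at$y[ci[1]], at$z[ci[1]])
        dist <- vnorm(a - d)
        if (dist > criteria$max_distance || dist < 1e-6) next
        v1 <- a0 - d; v2 <- a - d
        ang <- .rad2deg(acos(pmin(1, pmax(-1, sum(v1 * v2) /
                                            (vnorm(v1) * vnorm(v2))))))
        if (ang < criteria$min_angle) next
        ## minimal distance wins; lexicographic label order breaks ties
        ## (labels are visited sorted, strict < keeps the first)
        if (dist < best_dist - 1e-12) {
          best_dist <- dist; best_label <- lab
        }
      }
    }
    labels <- c(labels, best_label)
  }
  lev <- c(sort(names(aspecs)), "none")
  counts <- table(factor(labels, levels = lev))
  structure(list(donor = paste0(dspec$resno, ":", dspec$atoms),
                 partner_counts = stats::setNames(as.integer(counts),
                                                  names(counts)),
                 total = length(labels), excluded = excluded,
                 assignments = labels, criteria = criteria),
            class = "hbond_census")
}

#' @export
print.hbond_census <- function(x, ...) {
  cat(sprintf("<hbond_census> donor %s over %d protomer(s)", x$donor,
              x$total))
  if (length(x$excluded)) cat(sprintf(" (%d excluded)", length(x$excluded)))
  cat("\n")
  for (nm in names(x$partner_counts)) {
    cat(sprintf("  %-12s %d\n", nm, x$partner_counts[[nm]]))
  }
  invisible(x)
}
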