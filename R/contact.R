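## Geometric scoring of a placed side chain against its environment:
## steric clashes (van der Waals overlap beyond a tolerance), favorable
## van der Waals contacts (a shell around the radius sum) and geometric
## hydrogen bonds (heavy-atom distance + antecedent angle).

#' Hydrogen-bond acceptance criteria
#'
#' @param max_distance maximum donor-acceptor heavy-atom distance, Angstrom
#'   (0, 5].
#' @param min_angle minimum antecedent-donor-acceptor angle, degrees
#'   [0, 180]. In hydrogen-aware mode the D-H...A angle is used instead.
#' @param hydrogen_aware use explicit hydrogens when present.
#' @return An \code{hbond_criteria} object.
#' @export
hbond_criteria <- function(max_distance = 3.5, min_angle = 90,
                           hydrogen_aware = FALSE) {
  stopifnot(max_distance > 0, max_distance <= 5,
            min_angle >= 0, min_angle <= 180)
  structure(list(max_distance = max_distance, min_angle = min_angle,
                 hydrogen_aware = hydrogen_aware), class = "hbond_criteria")
}

.atom_key <- function(atoms) paste0(atoms$resno, ":", atoms$name)

.pair_frame <- function() {
  data.frame(probe_name = character(0), probe_resno = integer(0),
             env_name = character(0), env_resno = integer(0),
             distance = numeric(0), overlap = numeric(0),
             stringsAsFactors = FALSE)
}

## distance matrix probe x environment
.dist_matrix <- function(probe, env) {
  px <- as.matrix(probe[, c("x", "y", "z")])
  ex <- as.matrix(env[, c("x", "y", "z")])
  d2 <- outer(rowSums(px^2), rowSums(ex^2), `+`) - 2 * px %*% t(ex)
  sqrt(pmax(d2, 0))
}

.exclusion_mask <- function(probe, env, exclusions) {
  mask <- matrix(FALSE, nrow(probe), ncol = nrow(env))
  pk <- .atom_key(probe); ek <- .atom_key(env)
  ## self pairs: the same atom present on both sides
  mask <- outer(pk, ek, `==`)
  if (!is.null(exclusions) && nrow(exclusions)) {
    exk <- paste(exclusions[[1]], exclusions[[2]], sep = "~")
    pairk <- outer(pk, ek, paste, sep = "~")
    mask <- mask | matrix(pairk %in% exk, nrow(probe))
  }
  mask
}

.check_radii <- function(atoms, what) {
  heavy <- !isTRUE_vec(atoms$is_hydrogen)
  if (any(is.na(atoms$vdw[heavy]))) {
    stop("missing van der Waals radius on ", what, " atom(s): ",
         paste(utils::head(atoms$name[heavy & is.na(atoms$vdw)], 5),
               collapse = ", "), call. = FALSE)
  }
}

isTRUE_vec <- function(x) if (is.null(x)) FALSE else x %in% TRUE

.drop_h <- function(atoms, include_hydrogens) {
  if (include_hydrogens || is.null(atoms$is_hydrogen)) return(atoms)
  atoms[!atoms$is_hydrogen, , drop = FALSE]
}

#' Detect steric clashes between a probe and its environment
#'
#' A clash is an unordered heavy-atom pair whose distance falls short of
#' the van der Waals radius sum by more than \code{overlap_threshold}.
#' Bonded (1-2), angle (1-3) and dihedral (1-4) pairs supplied in
#' \code{exclusions} are skipped, as are identical atoms appearing on both
#' sides.
#'
#' @param probe,environment atom data frames with columns name, resno,
#'   x, y, z, vdw (as produced by the structure model / rotamer builder).
#' @param overlap_threshold Angstrom of overlap tolerated before a pair is
#'   called a clash (default 0.4, the severe-clash convention).
#' @param exclusions two-column data frame of excluded pair keys
#'   ("resno:name" for probe and environment sides); see
#'   \code{\link{bonded_exclusions}}.
#' @param include_hydrogens include hydrogen atoms (default FALSE).
#' @return Data frame of clashes: probe/env atom identities, distance,
#'   overlap (r_i + r_j - d).
#' @examples
#' a <- data.frame(name = "C1", resno = 1, x = 0, y = 0, z = 0, vdw = 1.7)
#' b <- data.frame(name = "C2", resno = 2, x = 2.9, y = 0, z = 0, vdw = 1.7)
#' detect_clashes(a, b)$overlap  # 0.5
#' @export
detect_clashes <- function(probe, environment, overlap_threshold = 0.4,
                           exclusions = NULL, include_hydrogens = FALSE) {
  probe <- .drop_h(probe, include_hydrogens)
  environment <- .drop_h(environment, include_hydrogens)
  if (!nrow(probe) || !nrow(environment)) return(.pair_frame())
  .check_radii(probe, "probe"); .check_radii(environment, "environment")
  d <- .dist_matrix(probe, environment)
  rsum <- outer(probe$vdw, environment$vdw, `+`)
  ov <- rsum - d
  hit <- ov > overlap_threshold & !.exclusion_mask(probe, environment,
                                                   exclusions)
  idx <- which(hit, arr.ind = TRUE)
  if (!nrow(idx)) return(.pair_frame())
  out <- data.frame(probe_name = probe$name[idx[, 1]],
                    probe_resno = probe$resno[idx[, 1]],
                    env_name = environment$name[idx[, 2]],
                    env_resno = environment$resno[idx[, 2]],
                    distance = d[idx], overlap = ov[idx],
                    stringsAsFactors = FALSE)
  out[order(-out$overlap), ]
}

#' Count favorable van der Waals contacts
#'
#' Pairs within a shell just beyond the radius sum: clash pairs (overlap
#' beyond \code{overlap_threshold}) and excluded bonded pairs are not
#' contacts; remaining pairs with d <= r_i + r_j + shell qualify.
#'
#' @inheritParams detect_clashes
#' @param shell shell width beyond the radius sum, Angstrom (default 0.5).
#' @return Data frame of contacts (same columns as clashes; overlap may be
#'   negative).
#' @export
count_vdw_contacts <- function(probe, environment, shell = 0.5,
                               overlap_threshold = 0.4, exclusions = NULL,
                               include_hydrogens = FALSE) {
  probe <- .drop_h(probe, include_hydrogens)
  environment <- .drop_h(environment, include_hydrogens)
  if (!nrow(probe) || !nrow(environment)) return(.pair_frame())
  .check_radii(probe, "probe"); .check_radii(environment, "environment")
  d <- .dist_matrix(probe, environment)
  rsum <- outer(probe$vdw, environment$vdw, `+`)
  ov <- rsum - d
  hit <- (ov <= overlap_threshold) & (d <= rsum + shell) &
    !.exclusion_mask(probe, environment, exclusions)
  idx <- which(hit, arr.ind = TRUE)
  if (!nrow(idx)) return(.pair_frame())
  out <- data.frame(probe_name = probe$name[idx[, 1]],
                    probe_resno = probe$resno[idx[, 1]],
                    env_name = environment$name[idx[, 2]],
                    env_resno = environment$resno[idx[, 2]],
                    distance = d[idx], overlap = ov[idx],
                    stringsAsFactors = FALSE)
  out[order(out$distance), ]
}

#' Extract hydrogen-bond donor/acceptor sites from an atom table
#'
#' Uses the built-in chemistry tables (\code{\link{hbond_donors}},
#' \code{\link{hbond_acceptors}}); a donor site carries its antecedent's
#' coordinates for the angle test. Atoms whose antecedent is absent are
#' dropped.
#'
#' @param atoms atom data frame (needs name, resno, resid, x, y, z).
#' @return List with \code{donors} and \code{acceptors} data frames.
#' @export
hbond_sites <- function(atoms) {
  atoms <- atoms[!isTRUE_vec(atoms$is_hydrogen) & !isTRUE_vec(atoms$hetatm), ,
                 drop = FALSE]
  don <- list(); acc <- list()
  for (rn in unique(atoms$resno)) {
    at <- atoms[atoms$resno == rn, , drop = FALSE]
    aa <- at$resid[1]
    if (!(aa %in% .aa3)) next
    dt <- hbond_donors(aa)
    for (dn in names(dt)) {
      i <- match(dn, at$name); j <- match(dt[[dn]], at$name)
      if (is.na(i) || is.na(j)) next
      don[[length(don) + 1]] <- data.frame(
        name = dn, resno = rn, resid = aa,
        x = at$x[i], y = at$y[i], z = at$z[i],
        ax = at$x[j], ay = at$y[j], az = at$z[j],
        stringsAsFactors = FALSE)
    }
    for (an in hbond_acceptors(aa)) {
      i <- match(an, at$name)
      if (is.na(i)) next
      acc[[length(acc) + 1]] <- data.frame(
        name = an, resno = rn, resid = aa,
        x = at$x[i], y = at$y[i], z = at$z[i],
        stringsAsFactors = FALSE)
    }
  }
  list(donors = if (length(don)) do.call(rbind, don) else
         data.frame(name = character(0), resno = integer(0),
                    resid = character(0), x = numeric(0), y = numeric(0),
                    z = numeric(0), ax = numeric(0), ay = numeric(0),
                    az = numeric(0)),
       acceptors = if (length(acc)) do.call(rbind, acc) else
         data.frame(name = character(0), resno = integer(0),
                    resid = character(0), x = numeric(0), y = numeric(0),
                    z = numeric(0)))
}

#' Detect geometric hydrogen bonds
#'
#' Heavy-atom mode: a donor-acceptor pair bonds when their distance is at
#' most \code{criteria$max_distance} and the antecedent-donor-acceptor
#' angle is at least \code{criteria$min_angle}. Donor and acceptor in the
#' same residue never pair.
#'
#' @param donors donor site data frame (see \code{\link{hbond_sites}}).
#' @param acceptors acceptor site data frame.
#' @param criteria an \code{\link{hbond_criteria}}.
#' @return Data frame: donor_resno, donor_name, acceptor_resno,
#'   acceptor_name, distance, angle.
#' @export
detect_hbonds <- function(donors, acceptors, criteria = hbond_criteria()) {
  out <- data.frame(donor_resno = integer(0), donor_name = character(0),
                    acceptor_resno = integer(0), acceptor_name = character(0),
                    distance = numeric(0), angle = numeric(0),
                    stringsAsFactors = FALSE)
  if (!nrow(donors) || !nrow(acceptors)) return(out)
  for (i in seq_len(nrow(donors))) {
    d <- as.numeric(donors[i, c("x", "y", "z")])
    a0 <- as.numeric(donors[i, c("ax", "ay", "az")])
    for (j in seq_len(nrow(acceptors))) {
      if (donors$resno[i] == acceptors$resno[j]) next
      a <- as.numeric(acceptors[j, c("x", "y", "z")])
      dist <- vnorm(a - d)
      if (dist > criteria$max_distance || dist < 1e-6) next
      v1 <- a0 - d; v2 <- a - d
      ang <- .rad2deg(acos(pmin(1, pmax(-1, sum(v1 * v2) /
                                          (vnorm(v1) * vnorm(v2))))))
      if (ang < criteria$min_angle) next
      out <- rbind(out, data.frame(
        donor_resno = donors$resno[i], donor_name = donors$name[i],
        acceptor_resno = acceptors$resno[j],
        acceptor_name = acceptors$name[j],
        distance = dist, angle = ang, stringsAsFactors = FALSE))
    }
  }
  out
}

#' Bonded-pair exclusions for a residue's side chain
#'
#' Enumerates the 1-2, 1-3 and 1-4 atom pairs, by bond-graph breadth-first
#' search, between the side-chain atoms of the residue at \code{position}
#' (with amino acid \code{amino_acid}) and the residue's own backbone plus
#' its peptide-bonded neighbors. Inter-residue pairs beyond the peptide
#' link are never excluded.
#'
#' @param position residue number.
#' @param amino_acid 3-letter code of the residue occupying the position.
#' @param prev_resno,next_resno numbers of the peptide-bonded neighbors
#'   (NA when absent).
#' @return Two-column data frame of "resno:name" pair keys.
#' @export
bonded_exclusions <- function(position, amino_acid,
                              prev_resno = position - 1L,
                              next_resno = position + 1L) {
  aa <- aa_three(amino_acid)
  key <- function(rn, nm) paste0(rn, ":", nm)
  edges <- lapply(residue_bonds(aa), function(b)
    c(key(position, b[1]), key(position, b[2])))
  if (!is.na(prev_resno)) {
    edges <- c(edges,
               list(c(key(prev_resno, "C"), key(position, "N")),
                    c(key(prev_resno, "CA"), key(prev_resno, "C")),
                    c(key(prev_resno, "O"), key(prev_resno, "C"))))
  }
  if (!is.na(next_resno)) {
    edges <- c(edges,
               list(c(key(position, "C"), key(next_resno, "N")),
                    c(key(next_resno, "N"), key(next_resno, "CA"))))
  }
  nodes <- unique(unlist(edges))
  adj <- lapply(stats::setNames(nodes, nodes), function(n) {
    unique(unlist(lapply(edges, function(e)
      if (e[1] == n) e[2] else if (e[2] == n) e[1])))
  })
  side <- key(position, sidechain_atom_names(aa))
  side <- intersect(side, nodes)
  pairs <- list()
  for (s in side) {
    ## BFS to depth 3
    depth <- stats::setNames(rep(Inf, length(nodes)), nodes)
    depth[s] <- 0
    frontier <- s
    for (dd in 1:3) {
      nxt <- unique(unlist(adj[frontier]))
      nxt <- nxt[depth[nxt] > dd]
      if (!length(nxt)) break
      depth[nxt] <- dd
      frontier <- nxt
    }
    reach <- names(depth)[is.finite(depth) & depth > 0]
    if (length(reach)) {
      pairs[[s]] <- data.frame(probe = s, env = reach,
                               stringsAsFactors = FALSE)
    }
  }
  if (!length(pairs)) {
    return(data.frame(probe = character(0), env = character(0)))
  }
  do.call(rbind, pairs)
}

## ---- Rotamer scoring ---------------------------------------------------

#' Scan parameters
#'
#' Bundles the geometric thresholds used throughout a scan; every value is
#' echoed into reports.
#'
#' @param overlap_threshold clash overlap tolerance, Angstrom.
#' @param contact_shell contact shell beyond the radius sum, Angstrom.
#' @param env_radius environment radius around the mutated residue's CB
#'   (CA for Gly), Angstrom.
#' @param hbond \code{\link{hbond_criteria}}.
#' @param f_contact fraction of wild-type side-chain contacts a variant's
#'   best rotamer must retain to avoid a loss-of-van-der-Waals call.
#' @param clash_free_fraction_min minimum fraction of clash-free rotamers
#'   below which a steric-clash label is assigned.
#' @return A \code{scan_params} object.
#' @export
scan_params <- function(overlap_threshold = 0.4, contact_shell = 0.5,
                        env_radius = 8, hbond = hbond_criteria(),
                        f_contact = 0.6, clash_free_fraction_min = 0.5) {
  structure(list(overlap_threshold = overlap_threshold,
                 contact_shell = contact_shell, env_radius = env_radius,
                 hbond = hbond, f_contact = f_contact,
                 clash_free_fraction_min = clash_free_fraction_min),
            class = "scan_params")
}

.environment_atoms <- function(protomer, position, env_radius,
                               center = NULL) {
  at <- protomer$atoms
  res <- get_residue(protomer, position)
  if (is.null(center)) {
    cn <- if ("CB" %in% res$atoms$name) "CB" else "CA"
    center <- as.numeric(res$atoms[match(cn, res$atoms$name),
                                   c("x", "y", "z")])
  }
  d <- sqrt((at$x - center[1])^2 + (at$y - center[2])^2 +
              (at$z - center[3])^2)
  near_res <- unique(at$resno[d <= env_radius])
  keep <- at$resno %in% near_res & !at$is_hydrogen &
    !(toupper(at$resid) %in% c("HOH", "WAT"))
  env <- at[keep, , drop = FALSE]
  ## drop the target residue's own side chain; keep its backbone
  own_side <- env$resno == position & !env$hetatm &
    !(env$name %in% c("N", "CA", "C", "O", "OXT"))
  env[!own_side, , drop = FALSE]
}

.sidechain_of <- function(protomer, position) {
  at <- protomer$atoms
  sel <- at$resno == position & !at$hetatm &
    !(at$name %in% c("N", "CA", "C", "O", "OXT")) & !at$is_hydrogen
  at[sel, , drop = FALSE]
}

.contact_report <- function(probe, env, position, amino_acid, protomer,
                            params) {
  rnos <- residue_numbers(protomer)
  i <- match(position, rnos)
  excl <- bonded_exclusions(position, amino_acid,
                            prev_resno = if (i > 1) rnos[i - 1] else NA,
                            next_resno = if (i < length(rnos)) rnos[i + 1]
                                         else NA)
  clashes <- detect_clashes(probe, env, params$overlap_threshold, excl)
  ## hydrogen bonds involving the probe side chain
  res_bb <- protomer$atoms[protomer$atoms$resno == position &
                             !protomer$atoms$hetatm &
                             protomer$atoms$name %in% c("N", "CA", "C", "O"),
                           , drop = FALSE]
  sites_probe <- hbond_sites(rbind(res_bb[, names(protomer$atoms)],
                                   .fill_atom_cols(probe, protomer,
                                                   position, amino_acid)))
  ## restrict probe sites to side-chain atoms
  side_names <- sidechain_atom_names(amino_acid)
  sites_probe$donors <- sites_probe$donors[
    sites_probe$donors$name %in% side_names, , drop = FALSE]
  sites_probe$acceptors <- sites_probe$acceptors[
    sites_probe$acceptors$name %in% side_names, , drop = FALSE]
  sites_env <- hbond_sites(env)
  hb <- rbind(detect_hbonds(sites_probe$donors, sites_env$acceptors,
                            params$hbond),
              detect_hbonds(sites_env$donors, sites_probe$acceptors,
                            params$hbond))
  ## pair-category priority: clash > hbond > contact
  pk <- function(r1, n1, r2, n2) paste0(pmin(paste0(r1, ":", n1),
                                             paste0(r2, ":", n2)), "~",
                                        pmax(paste0(r1, ":", n1),
                                             paste0(r2, ":", n2)))
  clash_keys <- pk(clashes$probe_resno, clashes$probe_name,
                   clashes$env_resno, clashes$env_name)
  if (nrow(hb)) {
    hb_keys <- pk(hb$donor_resno, hb$donor_name,
                  hb$acceptor_resno, hb$acceptor_name)
    hb <- hb[!(hb_keys %in% clash_keys), , drop = FALSE]
    hb_keys <- hb_keys[!(hb_keys %in% clash_keys)]
  } else hb_keys <- character(0)
  contacts <- count_vdw_contacts(probe, env, params$contact_shell,
                                 params$overlap_threshold, excl)
  if (nrow(contacts)) {
    ckeys <- pk(contacts$probe_resno, contacts$probe_name,
                contacts$env_resno, contacts$env_name)
    contacts <- contacts[!(ckeys %in% c(clash_keys, hb_keys)), ,
                         drop = FALSE]
  }
  structure(list(clashes = clashes, vdw_contacts = contacts, hbonds = hb,
                 n_clashes = nrow(clashes), n_contacts = nrow(contacts),
                 n_hbonds = nrow(hb),
                 environment = sort(unique(env$resno)),
                 params = params),
            class = "contact_report")
}

.fill_atom_cols <- function(probe, protomer, position, amino_acid) {
  tmpl <- protomer$atoms[0, ]
  n <- nrow(probe)
  if (!n) return(tmpl)
  data.frame(name = probe$name, element = probe$element,
             x = probe$x, y = probe$y, z = probe$z,
             altloc = "", occupancy = 1, resno = position,
             resid = amino_acid, chain = protomer$chain_id, insert = "",
             hetatm = FALSE, is_hydrogen = FALSE,
             vdw = probe$vdw, stringsAsFactors = FALSE)
}

#' @export
print.contact_report <- function(x, ...) {
  cat(sprintf("<contact_report> %d clash(es), %d vdW contact(s), %d H-bond(s); environment: %d residue(s)\n",
              x$n_clashes, x$n_contacts, x$n_hbonds, length(x$environment)))
  invisible(x)
}

#' Score one rotamer of a substitution against the template environment
#'
#' Builds the substituted side chain on the template backbone
#' (\code{\link{replace_residue}}), collects the environment (all residues
#' with any atom within \code{params$env_radius} of the wild-type residue's
#' CB, or CA for Gly; waters and hydrogens excluded; the target's own side
#' chain removed, its backbone retained behind 1-2/1-3/1-4 exclusions) and
#' returns the placed side chain's contact report together with the
#' wild-type side chain's own report for differencing.
#'
#' @param protomer template \code{protomer}.
#' @param variant a \code{variant_spec} (not a deletion).
#' @param rotamer a \code{rotamer} for the substituted amino acid.
#' @param params a \code{\link{scan_params}}.
#' @return List of class \code{rotamer_score}: \code{variant},
#'   \code{rotamer}, \code{report} (mutant) and \code{wt_report}.
#' @export
score_rotamer <- function(protomer, variant, rotamer,
                          params = scan_params()) {
  stopifnot(inherits(variant, "variant_spec"))
  res <- get_residue(protomer, variant$position)
  cn <- if ("CB" %in% res$atoms$name) "CB" else "CA"
  center <- as.numeric(res$atoms[match(cn, res$atoms$name),
                                 c("x", "y", "z")])
  env <- .environment_atoms(protomer, variant$position, params$env_radius,
                            center)
  wt_probe <- .sidechain_of(protomer, variant$position)
  wt_report <- .contact_report(wt_probe, env, variant$position,
                               res$amino_acid, protomer, params)
  mut <- replace_residue(protomer, variant, rotamer)
  probe <- .sidechain_of(mut, variant$position)
  report <- .contact_report(probe, env, variant$position,
                            variant$substitution, mut, params)
  structure(list(variant = variant, rotamer = rotamer, report = report,
                 wt_report = wt_report),
            class = "rotamer_score")
}
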