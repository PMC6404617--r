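## Synthetic fixtures: fully controlled toy systems for every analysis
## stage — a two-strand beta hairpin with an engineered Glu packing site,
## conformer ensembles with a prescribed hydrogen-bond partner partition,
## simple clash / reciprocal-H-bond pairs, and binomial count tables. No
## external structures needed.

## run code under a fixed seed without disturbing the caller's RNG stream
.with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

.random_rotation <- function() {
  ax <- stats::rnorm(3)
  rotation_about_axis(ax, stats::runif(1, 0, 360))
}

#' Build the mini-hairpin fixture
#'
#' Two short antiparallel beta strands with ideal backbone geometry. The
#' first strand carries a central Glu whose side chain, at the designated
#' chi, packs against the second strand at van der Waals contact (not
#' clash) distance. By construction the site discriminates substitutions
#' the way a tightly packed loop interface does: Gln (same reach) is
#' tolerated, the branched Val cannot avoid a clash in any rotamer, and
#' Gly loses the packing contacts. Moving the strands apart
#' (\code{separation} + ~2 Angstrom) opens the site and de-clashes Val.
#'
#' @param seq1,seq2 strand sequences (1-letter); \code{seq1} must contain
#'   exactly one E, the engineered site.
#' @param separation inter-strand offset along the packing axis, Angstrom.
#' @param shift register shift of strand 2 along the strand axis, Angstrom.
#' @param lateral offset of strand 2 in the strand-1 plane, Angstrom.
#' @param glu_chi designated chi of the template Glu (degrees).
#' @param seed integer; the fixture is deterministic, the seed only feeds
#'   the (tiny) coordinate jitter when \code{jitter > 0}.
#' @param jitter Gaussian coordinate noise, Angstrom (default 0).
#' @return A \code{structure3d} with a single protomer holding both
#'   segments (the opposing strand is numbered from 101), so the whole toy
#'   system can be scanned directly; attribute \code{"site"} gives the
#'   engineered residue number.
#' @export
make_mini_hairpin <- function(seq1 = "GAAAEAAG", seq2 = "GAAAAAAG",
                              separation = 0, shift = 0, lateral = 0,
                              glu_chi = c(180, 60, 0),
                              seed = 1L, jitter = 0) {
  s1 <- strsplit(seq1, "")[[1]]
  site <- which(s1 == "E")
  if (length(site) != 1) stop("seq1 must contain exactly one E",
                              call. = FALSE)
  chi1 <- vector("list", length(s1))
  chi1[[site]] <- glu_chi
  p1 <- build_peptide(s1, phi = -139, psi = 135, chi = chi1,
                      chain_id = "A")
  p2 <- build_peptide(strsplit(seq2, "")[[1]], phi = -139, psi = 135,
                      chain_id = "B")
  ## placement frame derived from strand 1: u = strand axis, d = direction
  ## of the engineered Glu's face (CA->CB, perpendicular component), so the
  ## second strand packs against the side the Glu points to
  ca1 <- as.matrix(p1$atoms[p1$atoms$name == "CA", c("x", "y", "z")])
  u <- ca1[nrow(ca1), ] - ca1[1, ]; u <- u / vnorm(u)
  res_site <- get_residue(p1, site)
  cab <- residue_coords(res_site, c("CA", "CB"))
  d <- cab["CB", ] - cab["CA", ]
  d <- d - sum(d * u) * u; d <- d / vnorm(d)
  w <- vcross(u, d)
  center <- colMeans(ca1)
  ## end-over-end flip about d reverses the strand direction (antiparallel)
  rot <- rotation_about_axis(d, 180)
  ca2 <- as.matrix(p2$atoms[p2$atoms$name == "CA", c("x", "y", "z")])
  c2 <- colMeans(ca2)
  target <- center + (7.0 + separation) * d + (shift - 2.0) * u +
    (lateral + 1.0) * w
  tr <- make_transform(rot, as.numeric(target - rot %*% c2))
  at <- p2$atoms
  xyz <- apply_transform(tr, as.matrix(at[, c("x", "y", "z")]))
  at$x <- xyz[, 1]; at$y <- xyz[, 2]; at$z <- xyz[, 3]
  p2$atoms <- at
  if (jitter > 0) {
    n1 <- nrow(p1$atoms); n2 <- nrow(p2$atoms)
    noise <- .with_seed(seed, matrix(stats::rnorm(3 * (n1 + n2), 0, jitter),
                                     n1 + n2))
    p1$atoms[, c("x", "y", "z")] <-
      p1$atoms[, c("x", "y", "z")] + noise[seq_len(n1), ]
    p2$atoms[, c("x", "y", "z")] <-
      p2$atoms[, c("x", "y", "z")] + noise[n1 + seq_len(n2), ]
  }
  ## one protomer: the opposing segment is numbered from 101 so the whole
  ## toy system forms a single scan template
  atB <- p2$atoms
  atB$resno <- atB$resno + 100L
  atB$chain <- "A"
  p <- .new_protomer("A", rbind(p1$atoms, atB),
                     source = "built:mini-hairpin")
  s <- as_structure3d(list(p), accession = "synthetic-hairpin")
  attr(s, "site") <- site
  s
}

#' Build a clash-pair fixture
#'
#' Two residues whose side chains overlap by a controlled amount: a probe
#' Val facing an opposing Ala CB at the requested gap.
#'
#' @param gap distance between the closest probe/environment heavy atoms,
#'   Angstrom.
#' @return A \code{structure3d} with one protomer of two residues.
#' @export
make_clash_pair <- function(gap = 2.8) {
  p1 <- build_peptide(c("V"), chi = list(180), chain_id = "A",
                      start_resno = 1L)
  p2 <- build_peptide(c("A"), chain_id = "A", start_resno = 5L)
  cg1 <- p1$atoms[p1$atoms$name == "CG1", c("x", "y", "z")]
  cb2 <- p2$atoms[p2$atoms$name == "CB", c("x", "y", "z")]
  dir <- c(0, 0, 1)
  target <- as.numeric(cg1) + gap * dir
  delta <- target - as.numeric(cb2)
  at <- p2$atoms
  at$x <- at$x + delta[1]; at$y <- at$y + delta[2]; at$z <- at$z + delta[3]
  at$resno <- at$resno  # numbering preserved
  p <- .new_protomer("A", rbind(p1$atoms, at), source = "built:clash-pair")
  as_structure3d(list(p), accession = "synthetic-clash-pair")
}

#' Build a reciprocal Asn-Asn hydrogen-bond fixture
#'
#' Two asparagines arranged so each donates from ND2 to the other's OD1 at
#' the requested donor-acceptor distance — the geometry of a reciprocal
#' amide pair stapling two loop elements together.
#'
#' @param distance donor-acceptor heavy-atom distance, Angstrom.
#' @return A \code{structure3d} with one protomer of two Asn residues.
#' @export
make_hbond_pair <- function(distance = 2.9) {
  p1 <- build_peptide("N", chi = list(c(-60, -30)), chain_id = "A",
                      start_resno = 1L)
  p2 <- build_peptide("N", chi = list(c(-60, -30)), chain_id = "A",
                      start_resno = 5L)
  ## rotate the second Asn 180 about z so the amides face each other,
  ## then translate so ND2(1)->OD1(2) and ND2(2)->OD1(1) both sit at the
  ## requested distance (symmetric placement about the midpoint)
  rot <- rotation_about_axis(c(1, 0, 0), 180)
  at <- p2$atoms
  xyz <- apply_transform(make_transform(rot, c(0, 0, 0)),
                         as.matrix(at[, c("x", "y", "z")]))
  at$x <- xyz[, 1]; at$y <- xyz[, 2]; at$z <- xyz[, 3]
  nd2_1 <- as.numeric(p1$atoms[p1$atoms$name == "ND2", c("x", "y", "z")])
  od1_1 <- as.numeric(p1$atoms[p1$atoms$name == "OD1", c("x", "y", "z")])
  od1_2 <- as.numeric(at[at$name == "OD1", c("x", "y", "z")])
  nd2_2 <- as.numeric(at[at$name == "ND2", c("x", "y", "z")])
  ## solve translation t so |nd2_1 - (od1_2+t)| = d and |od1_1 - (nd2_2+t)| = d
  ## approximately: move the pair midpoint-to-midpoint then push apart
  mid1 <- (nd2_1 + od1_1) / 2
  mid2 <- (od1_2 + nd2_2) / 2
  t0 <- mid1 - mid2
  axis <- nd2_1 - od1_1
  axis <- if (vnorm(axis) > 1e-6) axis / vnorm(axis) else c(0, 1, 0)
  perp <- vcross(axis, c(0, 0, 1))
  if (vnorm(perp) < 1e-6) perp <- vcross(axis, c(0, 1, 0))
  perp <- perp / vnorm(perp)
  f <- function(s) {
    t <- t0 + s * perp
    max(abs(vnorm(nd2_1 - (od1_2 + t)) - distance),
        abs(vnorm(od1_1 - (nd2_2 + t)) - distance))
  }
  s_opt <- stats::optimize(f, c(0.5, 12))$minimum
  t <- t0 + s_opt * perp
  at$x <- at$x + t[1]; at$y <- at$y + t[2]; at$z <- at$z + t[3]
  p <- .new_protomer("A", rbind(p1$atoms, at), source = "built:hbond-pair")
  as_structure3d(list(p), accession = "synthetic-hbond-pair")
}

#' Build a conformer ensemble with a prescribed H-bond partner partition
#'
#' Replicates a small template peptide (a lysine donor flanked by two
#' acceptor carboxylates) under random rigid motions, setting the donor's
#' side-chain chi per copy so that its hydrogen-bond partner follows the
#' requested partition exactly; small chi noise is added and the resulting
#' assignment re-verified, so the census over the returned ensemble equals
#' the partition by construction.
#'
#' @param partition named integer vector over the partner labels
#'   \code{c(A = ..., B = ..., none = ...)}; its sum is the ensemble size.
#' @param seed integer seed (fixed seed, identical ensemble).
#' @param chi_noise s.d. of the per-copy chi perturbation, degrees.
#' @param criteria \code{\link{hbond_criteria}} used to engineer and
#'   verify assignments.
#' @return List of \code{protomer}s with attributes \code{"donor"},
#'   \code{"acceptors"} (specs for \code{\link{census_hbonds}}) and
#'   \code{"partition"}.
#' @export
make_ensemble <- function(partition = c(A = 5, none = 23, B = 8),
                          seed = 1L, chi_noise = 2,
                          criteria = hbond_criteria()) {
  if (any(partition < 0) || sum(partition) < 1) {
    stop("partition must be non-negative with positive sum", call. = FALSE)
  }
  if (!all(names(partition) %in% c("A", "B", "none")) ||
      anyDuplicated(names(partition))) {
    stop("partition names must be unique among A, B, none", call. = FALSE)
  }
  ## template: D(2) - K(3) - E(4) flanked by glycines; acceptors on both
  ## sides of the donor lysine
  tmpl <- build_peptide(c("G", "D", "K", "E", "G"),
                        phi = -90, psi = 0,
                        chi = list(NULL, c(-60, 0), NULL, c(-60, -60, 0),
                                   NULL),
                        chain_id = "A")
  donor <- "3:NZ"
  acceptors <- list(A = "2:OD1,OD2", B = "4:OE1,OE2")

  ## find lysine rotamers realizing each assignment class
  assign_of <- function(chi) {
    p <- tmpl
    mut <- replace_residue(p, variant_spec(3, "LYS", "LYS"),
                           rotamer("LYS", chi))
    census_hbonds(list(mut), donor, acceptors, criteria)$assignments
  }
  lib <- enumerate_rotamers("LYS")
  classes <- vapply(lib, function(r) assign_of(r$chi), character(1))
  pick <- lapply(c(A = "A", B = "B", none = "none"), function(cl)
    lib[classes == cl])
  for (cl in names(partition)) {
    if (partition[[cl]] > 0 && !length(pick[[cl]])) {
      stop("no lysine rotamer realizes partner class '", cl,
           "' on this template", call. = FALSE)
    }
  }

  .with_seed(seed, {
    labels <- rep(names(partition), times = partition)
    out <- vector("list", length(labels))
    for (i in seq_along(labels)) {
      cand <- pick[[labels[i]]]
      base <- cand[[1 + (i %% length(cand))]]
      chi <- base$chi
      for (try in 1:20) {
        chi_try <- base$chi + stats::rnorm(length(base$chi), 0, chi_noise)
        if (identical(assign_of(chi_try), labels[i])) { chi <- chi_try; break }
      }
      p <- replace_residue(tmpl, variant_spec(3, "LYS", "LYS"),
                           rotamer("LYS", chi))
      rot <- .random_rotation()
      tr <- make_transform(rot, stats::rnorm(3, 0, 10))
      at <- p$atoms
      xyz <- apply_transform(tr, as.matrix(at[, c("x", "y", "z")]))
      at$x <- xyz[, 1]; at$y <- xyz[, 2]; at$z <- xyz[, 3]
      p$atoms <- at
      p$chain_id <- "A"
      p$source <- sprintf("synthetic-ensemble:%d:%s", i, labels[i])
      out[[i]] <- p
    }
    attr(out, "donor") <- donor
    attr(out, "acceptors") <- acceptors
    attr(out, "partition") <- partition
    out
  })
}

#' Simulate an inclusion-count table
#'
#' Binomial draws of inclusion-bearing cells per variant and timepoint — a
#' toy emulator of the transfection assay the real table summarises.
#'
#' @param probs named list: variant -> length-2 numeric of true inclusion
#'   probabilities at 24 and 48 hr.
#' @param n named list: variant -> length-2 integer of cells counted
#'   (recycled from a scalar).
#' @param seed integer seed.
#' @return List of \code{inclusion_counts} (2 per variant).
#' @export
make_counts_table <- function(probs, n = 250, seed = 1L) {
  if (any(unlist(probs) < 0 | unlist(probs) > 1)) {
    stop("probabilities must lie in [0, 1]", call. = FALSE)
  }
  .with_seed(seed, {
    out <- list()
    for (v in names(probs)) {
      pv <- rep_len(probs[[v]], 2)
      nv <- rep_len(if (is.list(n)) n[[v]] else n, 2)
      for (k in 1:2) {
        out[[length(out) + 1]] <- inclusion_counts(
          v, c(24, 48)[k], nv[k], stats::rbinom(1, nv[k], pv[k]))
      }
    }
    out
  })
}
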