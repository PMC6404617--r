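## Consequence classification: condense per-rotamer contact reports into a
## per-variant call using the vocabulary STERIC_CLASH / LOSS_VDW /
## LOSS_HBOND / NONE. Deletions are handled by a rule-based register-shift
## path, never geometrically.

.label_levels <- c("NONE", "LOSS_HBOND", "LOSS_VDW", "STERIC_CLASH")

#' Severity rank of a consequence call
#'
#' NONE < LOSS_HBOND = LOSS_VDW < STERIC_CLASH; a call's severity is the
#' maximum over its labels.
#'
#' @param call a \code{consequence_call} (or a character vector of labels).
#' @return Integer severity (0 none, 1 loss labels, 2 steric clash).
#' @export
call_severity <- function(call) {
  labels <- if (inherits(call, "consequence_call")) call$labels else call
  sev <- c(NONE = 0L, LOSS_HBOND = 1L, LOSS_VDW = 1L, STERIC_CLASH = 2L)
  max(sev[labels])
}

#' Human-readable consequence string
#'
#' Renders labels in the report vocabulary ("None", "Loss of van der
#' Waals", "Steric clash", "Loss of H-bonds"), comma-separated in the
#' order loss-of-vdW, steric clash, loss-of-H-bonds.
#'
#' @param call a \code{consequence_call} or character label vector.
#' @return Single string.
#' @export
consequence_string <- function(call) {
  labels <- if (inherits(call, "consequence_call")) call$labels else call
  if (identical(labels, "NONE")) return("None")
  words <- c(LOSS_VDW = "Loss of van der Waals",
             STERIC_CLASH = "Steric clash",
             LOSS_HBOND = "Loss of H-bonds")
  paste(words[intersect(names(words), labels)], collapse = ", ")
}

## normalise an expected-label string (Table-1 style or internal codes)
## to the internal label set, for concordance
.parse_labels <- function(x) {
  if (is.na(x) || !nzchar(trimws(x)) || toupper(trimws(x)) %in%
        c("N/A", "NA")) return(NA)
  parts <- trimws(strsplit(x, ",", fixed = TRUE)[[1]])
  out <- vapply(parts, function(p) {
    pu <- toupper(p)
    pu <- gsub("ä", "A", pu)  # tolerate umlaut spellings
    if (pu %in% .label_levels) return(pu)
    if (grepl("NONE", pu)) return("NONE")
    if (grepl("CLASH", pu)) return("STERIC_CLASH")
    if (grepl("H-BOND|HBOND|HYDROGEN", pu)) return("LOSS_HBOND")
    if (grepl("WAALS|VDW|VAN DER", pu)) return("LOSS_VDW")
    stop("cannot interpret consequence label '", p, "'", call. = FALSE)
  }, character(1))
  sort(unique(out))
}

#' Classify the structural consequence of one variant
#'
#' For a deletion, returns the rule-based loss-of-H-bonds call: removing a
#' residue shifts everything C-terminal out of register with its
#' stabilising hydrogen-bond partners, an argument made from sequence
#' register rather than coordinates. For a substitution, every enumerated
#' rotamer is built on the template backbone and scored against the local
#' environment; the labels are assigned as:
#' \itemize{
#'   \item STERIC_CLASH when no rotamer is clash-free, or (secondary label)
#'     when the clash-free fraction is below
#'     \code{params$clash_free_fraction_min} and the best clash-free
#'     rotamer still triggers a loss label — the "depending on the rotamer
#'     examined" situation;
#'   \item LOSS_VDW when the wild-type side chain makes contacts and the
#'     best rotamer retains fewer than \code{params$f_contact} of them;
#'   \item LOSS_HBOND when the wild-type side chain's template hydrogen
#'     bonds cannot be matched in number by any clash-free rotamer;
#'   \item NONE when nothing triggers.
#' }
#' The best rotamer is the clash-free one with most contacts (ties: most
#' H-bonds, then enumeration order); with no clash-free rotamer, the one
#' with fewest clashes.
#'
#' @param protomer template \code{protomer}.
#' @param variant a \code{variant_spec} or variant string ("E40G",
#'   "E133del").
#' @param library a \code{rotamer_library} (library mode) — see
#'   \code{\link{enumerate_rotamers}}.
#' @param params a \code{\link{scan_params}}.
#' @param mode rotamer enumeration mode, "library" or "grid".
#' @return A \code{consequence_call}: \code{variant}, \code{labels},
#'   \code{rule_based}, \code{evidence} (per-rotamer data frame),
#'   \code{best} (index + summary), \code{wt} (wild-type side-chain
#'   counts), \code{clash_free_fraction}, \code{thresholds_used}.
#' @export
classify_variant <- function(protomer, variant,
                             library = default_rotamer_library(),
                             params = scan_params(),
                             mode = c("library", "grid")) {
  mode <- match.arg(mode)
  if (is.character(variant)) variant <- parse_variant(variant)
  stopifnot(inherits(variant, "variant_spec"))

  if (variant$substitution == "DEL") {
    res <- get_residue(protomer, variant$position)
    if (res$amino_acid != variant$wild_type) {
      stop(sprintf("template residue %d is %s, not the expected %s",
                   variant$position, res$amino_acid, variant$wild_type),
           call. = FALSE)
    }
    return(structure(list(
      variant = variant, labels = "LOSS_HBOND", rule_based = TRUE,
      evidence = data.frame(),
      best = NULL, wt = NULL, clash_free_fraction = NA_real_,
      note = paste("in-frame deletion: residues C-terminal to the site",
                   "shift out of register with their stabilising",
                   "hydrogen-bond partners"),
      thresholds_used = params), class = "consequence_call"))
  }

  res <- get_residue(protomer, variant$position)
  if (res$amino_acid != variant$wild_type) {
    stop(sprintf("template residue %d is %s, not the expected %s",
                 variant$position, res$amino_acid, variant$wild_type),
         call. = FALSE)
  }

  rots <- enumerate_rotamers(variant$substitution, library = library,
                             mode = mode)
  cn <- if ("CB" %in% res$atoms$name) "CB" else "CA"
  center <- as.numeric(res$atoms[match(cn, res$atoms$name),
                                 c("x", "y", "z")])
  env <- .environment_atoms(protomer, variant$position, params$env_radius,
                            center)
  wt_probe <- .sidechain_of(protomer, variant$position)
  wt_report <- .contact_report(wt_probe, env, variant$position,
                               res$amino_acid, protomer, params)

  ev <- vector("list", length(rots))
  for (i in seq_along(rots)) {
    mut <- replace_residue(protomer, variant, rots[[i]])
    probe <- .sidechain_of(mut, variant$position)
    rep_i <- .contact_report(probe, env, variant$position,
                             variant$substitution, mut, params)
    ev[[i]] <- data.frame(
      rotamer = rots[[i]]$label,
      chi = paste(sprintf("%.0f", rots[[i]]$chi), collapse = "/"),
      n_clashes = rep_i$n_clashes, n_contacts = rep_i$n_contacts,
      n_hbonds = rep_i$n_hbonds, stringsAsFactors = FALSE)
  }
  ev <- do.call(rbind, ev)

  clash_free <- ev$n_clashes == 0
  frac_free <- mean(clash_free)
  pool <- if (any(clash_free)) which(clash_free) else seq_len(nrow(ev))
  if (any(clash_free)) {
    best_i <- pool[order(-ev$n_contacts[pool], -ev$n_hbonds[pool])][1]
  } else {
    best_i <- pool[order(ev$n_clashes[pool], -ev$n_contacts[pool])][1]
  }

  labels <- character(0)
  if (!any(clash_free)) labels <- c(labels, "STERIC_CLASH")
  wt_contacts <- wt_report$n_contacts
  wt_hbonds <- wt_report$n_hbonds
  loss_vdw <- wt_contacts > 0 &&
    ev$n_contacts[best_i] < params$f_contact * wt_contacts
  if (loss_vdw) labels <- c(labels, "LOSS_VDW")
  hb_pool <- if (any(clash_free)) which(clash_free) else seq_len(nrow(ev))
  loss_hb <- wt_hbonds > 0 && max(ev$n_hbonds[hb_pool]) < wt_hbonds
  if (loss_hb) labels <- c(labels, "LOSS_HBOND")
  ## secondary clash label: rotamer-dependent outcome — a minority of
  ## rotamers avoid clashing and those that do still lose interactions
  if (any(clash_free) && frac_free < params$clash_free_fraction_min &&
      (loss_vdw || loss_hb)) {
    labels <- c(labels, "STERIC_CLASH")
  }
  if (!length(labels)) labels <- "NONE"
  labels <- intersect(.label_levels, unique(labels))

  structure(list(
    variant = variant, labels = labels, rule_based = FALSE,
    evidence = ev,
    best = list(index = best_i, rotamer = rots[[best_i]],
                n_clashes = ev$n_clashes[best_i],
                n_contacts = ev$n_contacts[best_i],
                n_hbonds = ev$n_hbonds[best_i]),
    wt = list(n_contacts = wt_contacts, n_hbonds = wt_hbonds,
              n_clashes = wt_report$n_clashes),
    clash_free_fraction = frac_free,
    thresholds_used = params), class = "consequence_call")
}

#' @export
print.consequence_call <- function(x, ...) {
  cat(sprintf("<consequence_call> %s: %s%s\n", format(x$variant),
              consequence_string(x),
              if (x$rule_based) " [rule-based]" else ""))
  if (!x$rule_based) {
    cat(sprintf("  rotamers: %d (%.0f%% clash-free); best: %d contacts, %d H-bonds, %d clashes; wild type: %d contacts, %d H-bonds\n",
                nrow(x$evidence), 100 * x$clash_free_fraction,
                x$best$n_contacts, x$best$n_hbonds, x$best$n_clashes,
                x$wt$n_contacts, x$wt$n_hbonds))
  }
  invisible(x)
}

#' Scan a panel of variants on a template
#'
#' The central entry point: classifies every variant of a panel against
#' one template protomer, collecting per-variant errors without aborting
#' the scan, and (when expected labels are supplied) tabulating
#' concordance.
#'
#' @param template a \code{structure3d} (its first protomer is used unless
#'   \code{chain} selects another) or a \code{protomer}.
#' @param variants character vector of variant strings, or list of
#'   \code{variant_spec}.
#' @param expected optional character vector of expected consequence
#'   labels, recycled against variants (Table-style strings such as
#'   "Loss of van der Waals, Steric clash" are understood).
#' @param library rotamer library.
#' @param params a \code{\link{scan_params}}.
#' @param mode rotamer enumeration mode.
#' @param chain chain id when \code{template} is a \code{structure3d}.
#' @return A \code{consequence_scan}: list with \code{calls} (named list of
#'   \code{consequence_call}), \code{errors} (named character),
#'   \code{table} (summary data frame incl. concordance when expected
#'   labels were given) and \code{params}.
#' @examples
#' hp <- make_mini_hairpin()
#' sc <- consequence_scan(hp, c("E5Q", "E5V", "E5G"))
#' summary(sc)
#' @export
consequence_scan <- function(template, variants, expected = NULL,
                             library = default_rotamer_library(),
                             params = scan_params(),
                             mode = c("library", "grid"),
                             chain = NULL) {
  mode <- match.arg(mode)
  protomer <- if (inherits(template, "structure3d")) {
    if (is.null(chain)) template$protomers[[1]]
    else template$protomers[[chain]]
  } else template
  stopifnot(inherits(protomer, "protomer"))
  if (is.character(variants)) variants <- lapply(variants, parse_variant)
  if (inherits(variants, "variant_spec")) variants <- list(variants)
  vnames <- vapply(variants, format, character(1))
  if (!is.null(expected)) expected <- rep_len(expected, length(variants))

  calls <- stats::setNames(vector("list", length(variants)), vnames)
  errors <- character(0)
  for (i in seq_along(variants)) {
    calls[i] <- list(tryCatch(
      classify_variant(protomer, variants[[i]], library = library,
                       params = params, mode = mode),
      error = function(e) {
        errors[[vnames[i]]] <<- conditionMessage(e)
        NULL
      }))
  }
  ok <- !vapply(calls, is.null, logical(1))

  tab <- data.frame(
    variant = vnames,
    call = vapply(seq_along(calls), function(i)
      if (ok[i]) consequence_string(calls[[i]]) else NA_character_,
      character(1)),
    rule_based = vapply(seq_along(calls), function(i)
      if (ok[i]) calls[[i]]$rule_based else NA, logical(1)),
    clash_free_fraction = vapply(seq_along(calls), function(i)
      if (ok[i]) calls[[i]]$clash_free_fraction else NA_real_, numeric(1)),
    stringsAsFactors = FALSE)
  if (!is.null(expected)) {
    tab$expected <- expected
    tab$concordant <- vapply(seq_along(calls), function(i) {
      if (!ok[i]) return(NA)
      expl <- .parse_labels(expected[i])
      if (all(is.na(expl))) return(NA)
      setequal(expl, calls[[i]]$labels)
    }, logical(1))
  }

  structure(list(calls = calls[ok], errors = errors, table = tab,
                 params = params, mode = mode),
            class = "consequence_scan")
}

#' @export
print.consequence_scan <- function(x, ...) {
  cat(sprintf("<consequence_scan> %d variant(s), %d error(s)\n",
              nrow(x$table), length(x$errors)))
  print(x$table, row.names = FALSE)
  if (length(x$errors)) {
    cat("errors:\n")
    for (nm in names(x$errors)) cat("  ", nm, ": ", x$errors[[nm]], "\n",
                                    sep = "")
  }
  invisible(x)
}

#' @export
summary.consequence_scan <- function(object, ...) {
  tab <- object$table
  cat(sprintf("Consequence scan of %d variant(s) (%s rotamers)\n",
              nrow(tab), object$mode))
  print(tab, row.names = FALSE)
  if ("concordant" %in% names(tab)) {
    conc <- tab$concordant
    cat(sprintf("concordance: %d/%d (%d not comparable)\n",
                sum(conc, na.rm = TRUE), sum(!is.na(conc)), sum(is.na(conc))))
  }
  invisible(tab)
}
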