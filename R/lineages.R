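# Patrilineal (Y-chromosome) lineage extraction.
#
# A patrilineal lineage is the set of patriline males connected by unbroken
# father -> son links to a common fatherless male root; it proxies a shared
# Y chromosome. Transmissions are *all* children (either sex) of lineage
# members, the unit counted by the transmission disequilibrium test.

#' Extract all patrilineal lineages
#'
#' One lineage per patriline male with no recorded father (the root);
#' members are the root plus every male reachable through father -> son
#' edges. Lineages partition the patriline males: every male with a recorded
#' father belongs to exactly one lineage (his root's). In permissive
#' (sex-permuted) pedigrees the father *role* defines the patriline
#' regardless of the permuted sex label.
#'
#' Transmission counts: `n_transmissions` counts every child (of any sex) of
#' a lineage member; children of unknown sex count toward `n_transmissions`
#' but toward neither `n_male` nor `n_female`, so
#' `n_transmissions == n_male + n_female` only when all transmissions have a
#' recorded sex.
#'
#' @param ped A [pedigree()].
#' @return A list of `lineage` objects, sorted by founder id, each with
#'   fields `founder_id`, `member_ids`, `transmitting_father_ids`,
#'   `n_transmissions`, `n_male`, `n_female`, `generations` (number of
#'   generations spanned by the members).
#' @examples
#' ped <- pedigree(c("M1", "M2", "M3", "F1", "M4", "F2"),
#'                 father = c(NA, "M1", "M1", "M1", "M2", "M2"),
#'                 sex = c("M", "M", "M", "F", "M", "F"))
#' lin <- patrilineal_lineages(ped)
#' lin[[1]]$member_ids
#' @export
patrilineal_lineages <- function(ped) {
  stopifnot(inherits(ped, "pedigree"))
  n <- nrow(ped)
  if (n == 0L) return(list())
  pm <- patriline_male(ped)
  fid <- match(ped$father, ped$id)
  gen <- ped_generations(ped)
  root_of <- rep(NA_integer_, n)
  for (i in order(gen)) {
    if (!pm[i]) next
    root_of[i] <- if (is.na(fid[i])) i else root_of[fid[i]]
  }
  roots <- sort(ped$id[pm & is.na(fid)], method = "radix")
  lapply(roots, function(rid) {
    r <- match(rid, ped$id)
    members <- which(!is.na(root_of) & root_of == r)
    member_ids <- sort(ped$id[members], method = "radix")
    counts <- transmission_counts(ped, member_ids)
    structure(c(list(founder_id = rid, member_ids = member_ids),
                counts,
                list(generations = max(gen[members]) - min(gen[members]) + 1L)),
              class = "lineage")
  })
}

transmission_counts <- function(ped, member_ids) {
  kids <- which(!is.na(ped$father) & ped$father %in% member_ids)
  list(
    transmitting_father_ids = sort(unique(ped$father[kids]), method = "radix"),
    n_transmissions = length(kids),
    n_male = sum(ped$sex[kids] == "male"),
    n_female = sum(ped$sex[kids] == "female")
  )
}

#' Count informative transmissions of a lineage
#'
#' Recounts, from the pedigree, every child whose father is a member of the
#' given lineage (the informative transmissions of that Y line), split by
#' recorded sex, plus the members with at least one child.
#'
#' @param ped A [pedigree()].
#' @param lineage A `lineage` from [patrilineal_lineages()].
#' @return List with `n_transmissions`, `n_male`, `n_female`,
#'   `transmitting_father_ids`. Unknown-sex children count toward
#'   `n_transmissions` only.
#' @export
informative_transmissions <- function(ped, lineage) {
  stopifnot(inherits(ped, "pedigree"), inherits(lineage, "lineage"))
  if (!all(lineage$member_ids %in% ped$id)) {
    stop("lineage members not found in pedigree")
  }
  counts <- transmission_counts(ped, lineage$member_ids)
  counts[c("n_transmissions", "n_male", "n_female", "transmitting_father_ids")]
}

#' Tabulate lineages
#'
#' Flattens a list of lineages into the lineage report table
#' (`lineage_id n_fathers n_transmissions n_male n_female generations`).
#'
#' @param lineages List of `lineage` objects.
#' @return A data.frame, one row per lineage.
#' @export
lineage_table <- function(lineages) {
  data.frame(
    lineage_id = vapply(lineages, `[[`, "", "founder_id"),
    n_fathers = vapply(lineages, function(l) length(l$transmitting_father_ids), 0L),
    n_transmissions = vapply(lineages, `[[`, 0L, "n_transmissions"),
    n_male = vapply(lineages, `[[`, 0L, "n_male"),
    n_female = vapply(lineages, `[[`, 0L, "n_female"),
    generations = vapply(lineages, `[[`, 0L, "generations"),
    stringsAsFactors = FALSE
  )
}

#' @export
print.lineage <- function(x, ...) {
  cat(sprintf("<lineage> root %s: %d members, %d fathers, %d transmissions (%d M / %d F), %d generations\n",
              x$founder_id, length(x$member_ids),
              length(x$transmitting_father_ids),
              x$n_transmissions, x$n_male, x$n_female, x$generations))
  invisible(x)
}
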