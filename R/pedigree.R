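# Pedigree data model, PED-style I/O, validation and graph queries.
#
# A pedigree is a data.frame with character columns id, father, mother and
# sex ("male"/"female"/"unknown"), carrying attributes `ped_mode` ("strict"
# or "permissive") and `provenance`. Missing parents are NA internally and
# "0" on disk. Strict mode additionally requires every recorded father to be
# male and every recorded mother to be female; permissive mode waives that,
# which is what sex-permuted pedigrees need.

SEX_LEVELS <- c("male", "female", "unknown")

parse_sex <- function(x) {
  x <- tolower(trimws(as.character(x)))
  out <- rep(NA_character_, length(x))
  out[x %in% c("1", "m", "male")] <- "male"
  out[x %in% c("2", "f", "female")] <- "female"
  out[x %in% c("0", "u", "unknown", "na", "")] <- "unknown"
  out[is.na(x)] <- "unknown"
  if (anyNA(out)) {
    stop("unrecognised sex code(s): ",
         paste(unique(x[is.na(out)]), collapse = ", "))
  }
  out
}

normalize_parent <- function(x) {
  x <- trimws(as.character(x))
  x[!nzchar(x) | x == "0" | is.na(x)] <- NA_character_
  x
}

validate_pedigree <- function(df, mode) {
  if (nrow(df) == 0L) return(invisible(df))
  if (any(!nzchar(df$id) | is.na(df$id))) {
    stop("individual ids must be non-empty strings")
  }
  dup <- df$id[duplicated(df$id)]
  if (length(dup)) {
    stop(sprintf("duplicate individual id: %s", dup[[1L]]))
  }
  for (col in c("father", "mother")) {
    ref <- df[[col]]
    bad <- !is.na(ref) & !(ref %in% df$id)
    if (any(bad)) {
      stop(sprintf("unknown parent reference: %s (as %s)",
                   ref[bad][[1L]], col))
    }
  }
  fid <- match(df$father, df$id)
  mid <- match(df$mother, df$id)
  # Kahn-style peel: an individual is placeable once both recorded parents are.
  done <- logical(nrow(df))
  repeat {
    ready <- !done &
      (is.na(fid) | done[ifelse(is.na(fid), 1L, fid)]) &
      (is.na(mid) | done[ifelse(is.na(mid), 1L, mid)])
    if (!any(ready)) break
    done[ready] <- TRUE
  }
  if (!all(done)) {
    stop(sprintf("cyclic ancestry involving: %s",
                 paste(utils::head(df$id[!done], 5L), collapse = ", ")))
  }
  if (mode == "strict") {
    fathers <- unique(df$father[!is.na(df$father)])
    notmale <- fathers[df$sex[match(fathers, df$id)] != "male"]
    if (length(notmale)) {
      stop(sprintf("father %s is not recorded male (strict mode)",
                   notmale[[1L]]))
    }
    mothers <- unique(df$mother[!is.na(df$mother)])
    notfem <- mothers[df$sex[match(mothers, df$id)] != "female"]
    if (length(notfem)) {
      stop(sprintf("mother %s is not recorded female (strict mode)",
                   notfem[[1L]]))
    }
  }
  invisible(df)
}

new_pedigree <- function(df, mode, provenance) {
  rownames(df) <- NULL
  structure(df, class = c("pedigree", "data.frame"),
            ped_mode = mode, provenance = provenance)
}

#' Construct a pedigree
#'
#' Builds and validates a pedigree from parallel vectors. Parent codes `"0"`,
#' `""` and `NA` all mean "missing"; sex accepts `1/M/male`, `2/F/female`,
#' `0/U/unknown` (case-insensitive).
#'
#' @param id Character vector of unique individual ids.
#' @param father,mother Parent ids (or missing codes), recycled to
#'   `length(id)`.
#' @param sex Sex codes, recycled to `length(id)`.
#' @param mode `"strict"` requires recorded fathers to be male and mothers
#'   female; `"permissive"` waives the parental-sex consistency check (needed
#'   for sex-permuted pedigrees, which may place a female in a father role).
#'   Both modes require unique ids, resolvable parent references and acyclic
#'   ancestry.
#' @param provenance Free-text label recorded on the object.
#' @return A `pedigree`: a data.frame with columns `id`, `father`, `mother`,
#'   `sex` and attributes `ped_mode`, `provenance`.
#' @examples
#' ped <- pedigree(c("f", "m", "c"), c(NA, NA, "f"), c(NA, NA, "m"),
#'                 c("M", "F", "M"))
#' founders(ped)
#' @export
pedigree <- function(id, father = NA_character_, mother = NA_character_,
                     sex = "unknown", mode = c("strict", "permissive"),
                     provenance = "") {
  mode <- match.arg(mode)
  id <- as.character(id)
  n <- length(id)
  df <- data.frame(
    id = id,
    father = normalize_parent(rep_len(as.character(father), n)),
    mother = normalize_parent(rep_len(as.character(mother), n)),
    sex = parse_sex(rep_len(sex, n)),
    stringsAsFactors = FALSE
  )
  validate_pedigree(df, mode)
  new_pedigree(df, mode, provenance)
}

#' @export
print.pedigree <- function(x, ...) {
  cat(sprintf("<pedigree> %d individuals (%d male, %d female, %d unknown), mode=%s\n",
              nrow(x), sum(x$sex == "male"), sum(x$sex == "female"),
              sum(x$sex == "unknown"), attr(x, "ped_mode")))
  prov <- attr(x, "provenance")
  if (nzchar(prov)) cat("provenance:", prov, "\n")
  invisible(x)
}

#' Read a pedigree from a PED-style trio table
#'
#' Expects whitespace- or tab-separated columns `id father mother sex`;
#' a header line and `#`-prefixed comment lines are ignored. `"0"` or an
#' empty field denotes a missing parent.
#'
#' @param source File path or connection.
#' @inheritParams pedigree
#' @return A validated [pedigree()].
#' @export
read_pedigree <- function(source, mode = c("strict", "permissive")) {
  mode <- match.arg(mode)
  lines <- readLines(source)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (length(lines) &&
      identical(tolower(strsplit(lines[[1L]], "[ \t]+")[[1L]][1:4]),
                c("id", "father", "mother", "sex"))) {
    lines <- lines[-1L]
  }
  if (!length(lines)) {
    return(pedigree(character(0), mode = mode,
                    provenance = "empty pedigree file"))
  }
  # single tabs preserve empty (missing-parent) fields; otherwise split on
  # whitespace runs
  tok <- lapply(lines, function(l) {
    if (grepl("\t", l, fixed = TRUE)) {
      strsplit(l, "\t", fixed = TRUE)[[1L]]
    } else {
      strsplit(l, " +")[[1L]]
    }
  })
  bad <- which(lengths(tok) < 4L)
  if (length(bad)) {
    stop(sprintf("malformed pedigree line %d: expected 4 columns", bad[[1L]]))
  }
  m <- do.call(rbind, lapply(tok, `[`, 1:4))
  pedigree(m[, 1L], m[, 2L], m[, 3L], m[, 4L], mode = mode,
           provenance = if (is.character(source)) source else "connection")
}

#' Write a pedigree in canonical PED-style form
#'
#' Output is byte-stable: a fixed header, rows sorted by id (C locale),
#' missing parents written as `0` and sex coded 1/2/0.
#'
#' @param ped A [pedigree()].
#' @param sink File path or connection.
#' @return Invisibly, the lines written.
#' @export
write_pedigree <- function(ped, sink) {
  stopifnot(inherits(ped, "pedigree"))
  header <- "id\tfather\tmother\tsex"
  if (nrow(ped)) {
    o <- order(ped$id, method = "radix")
    sexcode <- c(male = "1", female = "2", unknown = "0")[ped$sex[o]]
    body <- paste(ped$id[o],
                  ifelse(is.na(ped$father[o]), "0", ped$father[o]),
                  ifelse(is.na(ped$mother[o]), "0", ped$mother[o]),
                  sexcode, sep = "\t")
    lines <- c(header, body)
  } else {
    lines <- header
  }
  writeLines(lines, sink)
  invisible(lines)
}

#' Founders and patriline roots
#'
#' `founders()` returns ids with neither parent recorded. `patriline_roots()`
#' returns the roots of Y-chromosome lineages: patriline males (recorded
#' male, or occupying a father role in a permissive pedigree) with no
#' recorded father.
#'
#' @param ped A [pedigree()].
#' @return Character vector of ids (sorted, C locale).
#' @export
founders <- function(ped) {
  stopifnot(inherits(ped, "pedigree"))
  sort(ped$id[is.na(ped$father) & is.na(ped$mother)], method = "radix")
}

# Patriline-male predicate: recorded male, or in a father role. The second
# clause only matters in permissive (sex-permuted) pedigrees, where lineage
# membership follows the father role regardless of the permuted label.
patriline_male <- function(ped) {
  ped$sex == "male" | ped$id %in% ped$father
}

#' @rdname founders
#' @export
patriline_roots <- function(ped) {
  stopifnot(inherits(ped, "pedigree"))
  sort(ped$id[patriline_male(ped) & is.na(ped$father)], method = "radix")
}

#' Generation depth of each individual
#'
#' Founders (no recorded parents) are generation 0; everyone else is one more
#' than the deepest recorded parent.
#'
#' @param ped A [pedigree()].
#' @return Integer vector aligned with `ped$id`.
#' @export
ped_generations <- function(ped) {
  n <- nrow(ped)
  fid <- match(ped$father, ped$id)
  mid <- match(ped$mother, ped$id)
  gen <- rep(NA_integer_, n)
  gen[is.na(fid) & is.na(mid)] <- 0L
  while (anyNA(gen)) {
    ready <- is.na(gen) &
      (is.na(fid) | !is.na(gen[ifelse(is.na(fid), 1L, fid)])) &
      (is.na(mid) | !is.na(gen[ifelse(is.na(mid), 1L, mid)]))
    if (!any(ready)) stop("cyclic ancestry: generations undefined")
    pg <- pmax(ifelse(is.na(fid[ready]), -1L, gen[ifelse(is.na(fid[ready]), 1L, fid[ready])]),
               ifelse(is.na(mid[ready]), -1L, gen[ifelse(is.na(mid[ready]), 1L, mid[ready])]))
    gen[ready] <- pg + 1L
  }
  gen
}

# Undirected relationship graph: one node per individual, one edge per
# recorded parent-child relationship.
ped_igraph <- function(ped) {
  from <- c(ped$father, ped$mother)
  to <- c(ped$id, ped$id)
  keep <- !is.na(from)
  igraph::graph_from_data_frame(
    data.frame(from = from[keep], to = to[keep], stringsAsFactors = FALSE),
    directed = FALSE,
    vertices = data.frame(name = ped$id, stringsAsFactors = FALSE)
  )
}

#' Undirected pedigree distance
#'
#' Length of the shortest undirected path between two individuals using only
#' parent-child edges: 1 for parent/child, 2 for (half-)siblings or
#' grandparent/grandchild, 4 for first cousins.
#'
#' @param ped A [pedigree()].
#' @param a,b Individual ids.
#' @param max_radius Maximum radius of interest; paths longer than this (or
#'   disconnected pairs) return `Inf` ("beyond").
#' @return A number of edges, or `Inf`.
#' @export
undirected_distance <- function(ped, a, b, max_radius = Inf) {
  stopifnot(inherits(ped, "pedigree"), max_radius >= 0)
  for (x in c(a, b)) {
    if (!x %in% ped$id) stop(sprintf("unknown individual id: %s", x))
  }
  d <- suppressWarnings(igraph::distances(ped_igraph(ped), v = a, to = b))[1L, 1L]
  if (!is.finite(d) || d > max_radius) Inf else as.numeric(d)
}
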