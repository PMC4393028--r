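#' Construct a pedigree
#'
#' A validated parentage table. Unknown parents are `NA` (or `"0"` / empty
#' strings in input files). Validation rejects cycles (no individual may be
#' its own ancestor) and sex-inconsistent use of an id as both sire and dam.
#'
#' @param records Data frame with columns `id`, `sire`, `dam` (and any
#'   extras, e.g. `generation`, which are kept).
#' @param monoecious If `TRUE`, skip the sex-consistency check (an id may
#'   appear in both parent roles, as in hermaphroditic or simulated
#'   monoecious populations). Default `FALSE`.
#' @return A tibble of class `pedigree`.
#' @export
pedigree <- function(records, monoecious = FALSE) {
  ped <- tibble::as_tibble(records)
  stopifnot(all(c("id", "sire", "dam") %in% names(ped)))
  for (col in c("id", "sire", "dam")) {
    v <- as.character(ped[[col]])
    v[v %in% c("0", "")] <- NA_character_
    ped[[col]] <- v
  }
  if (anyDuplicated(ped$id)) stop("duplicate individual ids in pedigree")
  if (!monoecious) {
    sires <- stats::na.omit(ped$sire)
    dams <- stats::na.omit(ped$dam)
    both <- intersect(sires, dams)
    if (length(both) > 0) {
      stop("id(s) used as both sire and dam: ", paste(both, collapse = ", "))
    }
  }
  # acyclicity via Kahn's algorithm on the parent -> offspring DAG
  known <- ped$id
  parents <- lapply(seq_len(nrow(ped)), function(i) {
    p <- c(ped$sire[i], ped$dam[i])
    p[!is.na(p) & p %in% known]
  })
  names(parents) <- ped$id
  indeg <- vapply(parents, length, integer(1))
  queue <- names(indeg)[indeg == 0]
  seen <- 0L
  children <- split(rep(ped$id, lengths(parents)), unlist(parents))
  while (length(queue) > 0) {
    v <- queue[[1]]
    queue <- queue[-1]
    seen <- seen + 1L
    for (ch in children[[v]]) {
      indeg[ch] <- indeg[ch] - 1L
      if (indeg[ch] == 0L) queue <- c(queue, ch)
    }
  }
  if (seen < nrow(ped)) stop("pedigree contains a cycle")
  class(ped) <- c("pedigree", class(ped))
  ped
}

#' Read / write a pedigree CSV
#'
#' Columns `id,sire,dam` (plus extras); `0` or empty means unknown.
#'
#' @param path CSV path.
#' @param monoecious Passed to [pedigree()]: allow an id in both parent
#'   roles (e.g. pedigrees from monoecious simulations).
#' @return A `pedigree` (read) or `path` invisibly (write).
#' @export
read_pedigree_csv <- function(path, monoecious = FALSE) {
  pedigree(readr::read_csv(path, show_col_types = FALSE,
                           col_types = readr::cols(.default = "c")),
           monoecious = monoecious)
}

#' @rdname read_pedigree_csv
#' @param ped A `pedigree`.
#' @export
write_pedigree_csv <- function(ped, path) {
  out <- as.data.frame(ped)
  out$sire[is.na(out$sire)] <- "0"
  out$dam[is.na(out$dam)] <- "0"
  readr::write_csv(out, path)
  invisible(path)
}

# Truncate a pedigree at `max_depth` meioses above `id`: ancestors exactly at
# the horizon keep their id but lose their parents (treated as unknown
# founders). Returns a plain list id -> c(sire, dam) restricted to the
# ancestor closure.
truncate_pedigree <- function(ped, id, max_depth) {
  par <- function(x) {
    i <- match(x, ped$id)
    if (is.na(i)) c(NA_character_, NA_character_)
    else c(ped$sire[i], ped$dam[i])
  }
  out <- list()
  frontier <- stats::setNames(0L, id)
  depth_of <- c()
  while (length(frontier) > 0) {
    nm <- names(frontier)[1]
    d <- frontier[[1]]
    frontier <- frontier[-1]
    if (!is.null(depth_of[nm]) && !is.na(depth_of[nm]) && depth_of[nm] <= d) next
    depth_of[nm] <- d
    if (d >= max_depth) {
      out[[nm]] <- c(NA_character_, NA_character_)
    } else {
      p <- par(nm)
      out[[nm]] <- p
      for (pp in p[!is.na(p)]) {
        frontier <- c(frontier, stats::setNames(d + 1L, pp))
      }
    }
  }
  out
}

#' Pedigree inbreeding coefficient (Wright's F)
#'
#' F of an individual is half the additive relationship between its parents,
#' computed by the tabular method on the pedigree truncated `max_depth`
#' generations above the focal animal: ancestors beyond the horizon are
#' treated as unknown, unrelated, non-inbred founders. `max_depth = Inf`
#' uses the full recorded pedigree.
#'
#' @param ped A [pedigree()].
#' @param id Focal individual id (vectorised).
#' @param max_depth Generations of pedigree to use (default `Inf`).
#' @return Numeric vector of inbreeding coefficients.
#' @export
f_ped <- function(ped, id, max_depth = Inf) {
  stopifnot(max_depth >= 1)
  vapply(as.character(id), function(x) {
    if (!x %in% ped$id) stop("unknown id: ", x)
    sub <- truncate_pedigree(ped, x, max_depth)
    ids <- names(sub)
    # topological order: founders first
    ordered <- character(0)
    placed <- stats::setNames(rep(FALSE, length(ids)), ids)
    while (length(ordered) < length(ids)) {
      progress <- FALSE
      for (nm in ids[!placed[ids]]) {
        p <- sub[[nm]]
        p <- p[!is.na(p)]
        if (all(p %in% ordered)) {
          ordered <- c(ordered, nm)
          placed[nm] <- TRUE
          progress <- TRUE
        }
      }
      if (!progress) stop("pedigree contains a cycle")
    }
    a <- matrix(0, length(ordered), length(ordered),
                dimnames = list(ordered, ordered))
    for (nm in ordered) {
      p <- sub[[nm]]
      s <- p[1]
      d <- p[2]
      a_sd <- if (!is.na(s) && !is.na(d)) a[s, d] else 0
      a[nm, nm] <- 1 + 0.5 * a_sd
      for (other in ordered) {
        if (other == nm) break
        val <- 0
        if (!is.na(s)) val <- val + 0.5 * a[other, s]
        if (!is.na(d)) val <- val + 0.5 * a[other, d]
        a[nm, other] <- val
        a[other, nm] <- val
      }
    }
    a[x, x] - 1
  }, numeric(1), USE.NAMES = FALSE)
}

#' Pedigree completeness (MacCluer index)
#'
#' Mean over ancestral generations `g = 1..max_depth` of the fraction of
#' the `2^g` ancestor slots of that generation that are filled by a known
#' individual.
#'
#' @param ped A [pedigree()].
#' @param id Focal individual id (vectorised).
#' @param max_depth Generations to include.
#' @return Numeric vector in `[0, 1]`.
#' @export
completeness <- function(ped, id, max_depth) {
  stopifnot(max_depth >= 1)
  par <- function(x) {
    i <- match(x, ped$id)
    if (is.na(i)) c(NA_character_, NA_character_)
    else c(ped$sire[i], ped$dam[i])
  }
  vapply(as.character(id), function(x) {
    if (!x %in% ped$id) stop("unknown id: ", x)
    known <- numeric(max_depth)
    frontier <- x
    for (g in seq_len(max_depth)) {
      nxt <- character(0)
      for (nm in frontier) {
        p <- par(nm)
        nxt <- c(nxt, p[!is.na(p)])
      }
      known[g] <- length(nxt) / 2^g
      frontier <- nxt
      if (length(frontier) == 0) break
    }
    mean(known)
  }, numeric(1), USE.NAMES = FALSE)
}

#' Per-generation inbreeding rate from a mean pedigree F
#'
#' The simple average `mean_fped / n_generations`; the divisor is explicit
#' because the convention (depth vs depth - 1) differs between studies.
#'
#' @param mean_fped Mean pedigree inbreeding coefficient.
#' @param n_generations Number of generations to average over.
#' @return Per-generation inbreeding increase.
#' @export
delta_f_from_fped <- function(mean_fped, n_generations) {
  stopifnot(n_generations >= 1)
  mean_fped / n_generations
}
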