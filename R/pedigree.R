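#' Construct a pedigree from individual records
#'
#' @param individuals data.frame with columns `id`, `father`, `mother`
#'   (NA or "0" for unknown) and `sex` (1 = male, 2 = female, 0 = unknown).
#' @return a `Pedigree` object: list with `individuals` (including a derived
#'   `generation` column) and `trios` (data.frame `child`, `father`,
#'   `mother`, one row per child whose two parents are both present, sorted
#'   by child id).
#' @export
pedigree <- function(individuals) {
  req <- c("id", "father", "mother", "sex")
  if (!all(req %in% names(individuals)))
    stop("individuals must have columns ", paste(req, collapse = ", "))
  ind <- data.frame(id = as.character(individuals$id),
                    father = as.character(individuals$father),
                    mother = as.character(individuals$mother),
                    sex = individuals$sex,
                    stringsAsFactors = FALSE)
  ind$father[ind$father %in% c("0", "")] <- NA
  ind$mother[ind$mother %in% c("0", "")] <- NA
  if (anyDuplicated(ind$id))
    stop("duplicate individual id: ", ind$id[duplicated(ind$id)][1L])
  for (col in c("father", "mother")) {
    unknown <- !is.na(ind[[col]]) & !(ind[[col]] %in% ind$id)
    if (any(unknown))
      stop("unknown ", col, " id '", ind[[col]][unknown][1L],
           "' for individual ", ind$id[unknown][1L])
  }
  if (any(!is.na(ind$father) & ind$father == ind$id) ||
      any(!is.na(ind$mother) & ind$mother == ind$id))
    stop("individual listed as its own parent")

  # generation assignment doubles as cycle detection: a pedigree with an
  # ancestry cycle never resolves
  gen <- stats::setNames(rep(NA_integer_, nrow(ind)), ind$id)
  gen[is.na(ind$father) & is.na(ind$mother)] <- 1L
  repeat {
    parent_gen <- cbind(gen[ind$father], gen[ind$mother])
    ready <- is.na(gen) &
      (is.na(ind$father) | !is.na(parent_gen[, 1L])) &
      (is.na(ind$mother) | !is.na(parent_gen[, 2L]))
    if (!any(ready)) break
    gen[ready] <- pmax(parent_gen[ready, 1L], parent_gen[ready, 2L],
                       1L, na.rm = TRUE) + 1L
  }
  if (anyNA(gen))
    stop("pedigree contains an ancestry cycle involving: ",
         paste(ind$id[is.na(gen)], collapse = ", "))
  ind$generation <- unname(gen[ind$id])

  has_both <- !is.na(ind$father) & !is.na(ind$mother)
  trios <- data.frame(child = ind$id[has_both],
                      father = ind$father[has_both],
                      mother = ind$mother[has_both],
                      stringsAsFactors = FALSE)
  trios <- trios[order(trios$child), , drop = FALSE]
  rownames(trios) <- NULL
  structure(list(individuals = ind, trios = trios), class = "Pedigree")
}

#' @export
print.Pedigree <- function(x, ...) {
  cat("Pedigree:", nrow(x$individuals), "individuals,",
      max(x$individuals$generation), "generations,",
      nrow(x$trios), "trios\n")
  invisible(x)
}

#' Read a 6-column PED pedigree file
#'
#' Whitespace-delimited PED (family, individual, father, mother, sex,
#' phenotype); "0" marks an unknown parent.  The phenotype column is ignored
#' -- affection status plays no role in this analysis.
#'
#' @param path path to a PED file.
#' @return a [pedigree()] object.
#' @export
read_pedigree <- function(path) {
  ped <- utils::read.table(path, header = FALSE, stringsAsFactors = FALSE,
                           colClasses = "character")
  if (ncol(ped) < 6L)
    stop("PED file must have at least 6 columns, found ", ncol(ped))
  pedigree(data.frame(id = ped[[2L]], father = ped[[3L]], mother = ped[[4L]],
                      sex = as.integer(ped[[5L]]), stringsAsFactors = FALSE))
}

#' Write a pedigree as a 6-column PED file
#'
#' @param ped a [pedigree()] object.
#' @param path output path.
#' @param family family id written in column 1.
#' @return `path`, invisibly.
#' @export
write_pedigree <- function(ped, path, family = "FAM1") {
  ind <- ped$individuals
  out <- data.frame(family = family, id = ind$id,
                    father = ifelse(is.na(ind$father), "0", ind$father),
                    mother = ifelse(is.na(ind$mother), "0", ind$mother),
                    sex = ind$sex, phenotype = 0L)
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Default three-generation study family
#'
#' Six members: a founder couple, their two children, a married-in founder,
#' and a grandchild -- the smallest pedigree exercising trios in the second
#' and third generations.
#'
#' @return a [pedigree()] object with three trios.
#' @export
default_pedigree <- function() {
  pedigree(data.frame(
    id     = c("F1", "M1", "C1", "C2", "S1", "G1"),
    father = c(NA,   NA,   "F1", "F1", NA,   "C1"),
    mother = c(NA,   NA,   "M1", "M1", NA,   "S1"),
    sex    = c(1L,   2L,   1L,   2L,   2L,   1L),
    stringsAsFactors = FALSE))
}
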