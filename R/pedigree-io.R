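#' Construct a pedigree dataset
#'
#' Container for nuclear-family genotype data: an individuals table (family,
#' individual, father, mother, sex, phenotype), a genotype matrix of
#' minor-allele counts (individuals x markers, values 0/1/2/NA), and a marker
#' table (id, chromosome, position, minor and major allele labels).
#' Phenotype is coded 1 = affected, 0 = unaffected, NA = missing.
#'
#' @param individuals Data frame with character columns \code{family_id},
#'   \code{individual_id}, \code{father_id}, \code{mother_id} and columns
#'   \code{sex}, \code{phenotype}.
#' @param genotypes Integer matrix of minor-allele counts.
#' @param markers Data frame with columns \code{marker_id},
#'   \code{chromosome}, \code{position}, \code{allele_minor},
#'   \code{allele_major}.
#' @return Object of class \code{"pedigree_dataset"}.
#' @export
pedigree_dataset <- function(individuals, genotypes, markers) {
  genotypes <- as.matrix(genotypes)
  stopifnot(nrow(genotypes) == nrow(individuals),
            ncol(genotypes) == nrow(markers),
            all(genotypes %in% c(0L, 1L, 2L, NA)))
  for (col in c("family_id", "individual_id", "father_id", "mother_id"))
    individuals[[col]] <- as.character(individuals[[col]])
  # parent ids must be "0" or resolve within the same family
  key <- paste(individuals$family_id, individuals$individual_id)
  for (col in c("father_id", "mother_id")) {
    ref <- individuals[[col]]
    bad <- ref != "0" & !(paste(individuals$family_id, ref) %in% key)
    if (any(bad))
      stop("data error: ", col, " not found in family for individual(s) ",
           paste(individuals$individual_id[bad], collapse = ", "))
  }
  structure(list(individuals = individuals, genotypes = genotypes,
                 markers = markers),
            class = "pedigree_dataset")
}

#' @export
print.pedigree_dataset <- function(x, ...) {
  cat(sprintf("Pedigree dataset: %d individuals, %d families, %d markers\n",
              nrow(x$individuals), length(unique(x$individuals$family_id)),
              nrow(x$markers)))
  invisible(x)
}

VALID_ALLELES <- c("0", "1", "2", "A", "C", "G", "T")

#' Read PLINK text PED/MAP files
#'
#' Parses pedigree genotype data in the de-facto standard PLINK text format:
#' PED rows carry 6 leading columns (family, individual, father, mother,
#' sex, phenotype) followed by two allele columns per marker; MAP rows carry
#' chromosome, marker id, genetic distance and base-pair position.  The
#' minor allele of each marker is determined from founder allele counts
#' (individuals with both parent ids "0"; ties broken by lexical order of
#' the allele label), genotypes are converted to minor-allele counts, a
#' genotype with either allele "0" is missing, and phenotypes are recoded
#' 2 -> affected (1), 1 -> unaffected (0), 0 or -9 -> missing.
#'
#' @param ped,map File paths, connections, or character vectors of lines.
#' @return A \code{\link{pedigree_dataset}}.
#' @export
read_ped_map <- function(ped, map) {
  ped_lines <- read_text_lines(ped)
  map_lines <- read_text_lines(map)
  map_tok <- lapply(map_lines, split_ws)
  nc <- lengths(map_tok)
  if (any(nc != 4L))
    stop("parse error: MAP line ", which(nc != 4L)[1L],
         " has ", nc[nc != 4L][1L], " columns (expected 4)")
  markers <- data.frame(
    marker_id = vapply(map_tok, `[[`, "", 2L),
    chromosome = vapply(map_tok, `[[`, "", 1L),
    position = as.integer(vapply(map_tok, `[[`, "", 4L)),
    allele_minor = NA_character_, allele_major = NA_character_,
    stringsAsFactors = FALSE)
  M <- nrow(markers)

  ped_tok <- lapply(ped_lines, split_ws)
  nc <- lengths(ped_tok)
  want <- 6L + 2L * M
  if (length(ped_tok) && any(nc != want))
    stop("parse error: PED line ", which(nc != want)[1L], " has ",
         nc[nc != want][1L], " columns (expected ", want, ")")
  n <- length(ped_tok)
  tokens <- if (n) do.call(rbind, ped_tok) else
    matrix(character(0), 0, want)
  individuals <- data.frame(
    family_id = tokens[, 1L], individual_id = tokens[, 2L],
    father_id = tokens[, 3L], mother_id = tokens[, 4L],
    sex = as.integer(tokens[, 5L]),
    phenotype = recode_phenotype(tokens[, 6L]),
    stringsAsFactors = FALSE)

  a1 <- tokens[, 6L + 2L * seq_len(M) - 1L, drop = FALSE]
  a2 <- tokens[, 6L + 2L * seq_len(M), drop = FALSE]
  bad <- !(a1 %in% VALID_ALLELES) | !(a2 %in% VALID_ALLELES)
  if (any(bad))
    stop("parse error: invalid allele code on PED line ",
         which(rowSums(bad) > 0)[1L])
  founder <- individuals$father_id == "0" & individuals$mother_id == "0"
  genotypes <- matrix(NA_integer_, n, M)
  for (j in seq_len(M)) {
    x1 <- a1[, j]; x2 <- a2[, j]
    obs <- c(x1, x2)
    labs <- sort(unique(obs[obs != "0"]))
    if (length(labs) > 2L)
      stop("data error: marker ", markers$marker_id[j], " has ",
           length(labs), " distinct alleles")
    if (length(labs) == 0L) next
    if (length(labs) == 1L) {
      # monomorphic in the file: the single label is the major allele
      markers$allele_major[j] <- labs
      genotypes[, j] <- ifelse(x1 == "0" | x2 == "0", NA_integer_, 0L)
      next
    }
    cnt <- c(sum(x1[founder] == labs[1L]) + sum(x2[founder] == labs[1L]),
             sum(x1[founder] == labs[2L]) + sum(x2[founder] == labs[2L]))
    # minor = less frequent among founders; lexical tie-break (labs sorted)
    minor <- if (cnt[2L] < cnt[1L]) labs[2L] else labs[1L]
    major <- setdiff(labs, minor)
    markers$allele_minor[j] <- minor
    markers$allele_major[j] <- major
    g <- (x1 == minor) + (x2 == minor)
    g[x1 == "0" | x2 == "0"] <- NA_integer_
    genotypes[, j] <- g
  }
  pedigree_dataset(individuals, genotypes, markers)
}

read_text_lines <- function(x) {
  if (is.character(x) && length(x) == 1L && file.exists(x)) readLines(x)
  else if (inherits(x, "connection")) readLines(x)
  else as.character(x)
}

split_ws <- function(line) strsplit(trimws(line), "[ \t]+")[[1L]]

recode_phenotype <- function(x) {
  out <- rep(NA_real_, length(x))
  out[x == "2"] <- 1
  out[x == "1"] <- 0
  out
}

#' Write PLINK text PED/MAP files
#'
#' Inverse of \code{\link{read_ped_map}}: emits genotype counts as allele
#' pairs (minor-allele label repeated \code{g} times), missing genotypes as
#' "0 0", phenotypes as 2/1/0, and the marker table as 4-column MAP lines.
#' Reading the written files back reproduces the dataset's genotype counts,
#' ids and phenotypes exactly, provided the dataset is minor-allele coded
#' with respect to its founders (as everything produced by this package is);
#' when founder allele counts tie, labels are assigned so that the reader's
#' lexical tie-break recovers the same counts.
#'
#' @param dataset A \code{\link{pedigree_dataset}}.
#' @param ped,map Optional output file paths; when omitted the lines are
#'   only returned.
#' @return List with character vectors \code{ped} and \code{map}, invisibly
#'   when files are written.
#' @export
write_ped_map <- function(dataset, ped = NULL, map = NULL) {
  stopifnot(inherits(dataset, "pedigree_dataset"))
  ind <- dataset$individuals
  G <- dataset$genotypes
  mk <- dataset$markers
  n <- nrow(ind); M <- nrow(mk)
  founder <- ind$father_id == "0" & ind$mother_id == "0"
  geno_cols <- character(0)
  if (M > 0L && n > 0L) {
    cols <- vector("list", M)
    for (j in seq_len(M)) {
      minor <- mk$allele_minor[j]
      major <- mk$allele_major[j]
      if (is.na(minor)) minor <- if (is.na(major) || major != "1") "1" else "2"
      if (is.na(major)) major <- if (minor != "1") "1" else "2"
      g <- G[, j]
      # if founder counts tie, emit the lexically-first label for the minor
      # allele so a reader's tie-break reproduces the counts
      cnt_minor <- sum(g[founder], na.rm = TRUE)
      n_f <- sum(founder & !is.na(g))
      if (n_f > 0L && cnt_minor == n_f && minor > major) {
        tmp <- minor; minor <- major; major <- tmp
      }
      a1 <- ifelse(is.na(g), "0", ifelse(g >= 1L, minor, major))
      a2 <- ifelse(is.na(g), "0", ifelse(g == 2L, minor, major))
      cols[[j]] <- paste(a1, a2)
    }
    geno_cols <- do.call(paste, cols)
  }
  phen <- ifelse(is.na(ind$phenotype), "0", ifelse(ind$phenotype == 1, "2", "1"))
  lead <- paste(ind$family_id, ind$individual_id, ind$father_id,
                ind$mother_id, ind$sex, phen)
  ped_lines <- if (n == 0L) character(0)
               else if (M == 0L) lead else paste(lead, geno_cols)
  map_lines <- if (M == 0L) character(0)
               else paste(mk$chromosome, mk$marker_id, 0, mk$position)
  if (!is.null(ped)) writeLines(ped_lines, ped)
  if (!is.null(map)) writeLines(map_lines, map)
  out <- list(ped = ped_lines, map = map_lines)
  if (is.null(ped) && is.null(map)) out else invisible(out)
}

#' Construct a nuclear family
#'
#' The unit of conditioning for all family-based statistics: either a
#' trio-like family (both parents typed, one or more offspring) or a sibship
#' without parental genotypes (used for discordant sibpairs).
#'
#' @param family_id Family label.
#' @param father,mother Parental genotype vectors (minor-allele counts), or
#'   \code{NULL} for a sibship without typed parents.
#' @param offspring Offspring genotype matrix, one row per offspring.
#' @param traits Offspring trait vector (1 affected, 0 unaffected, NA
#'   missing), same length as offspring rows.
#' @return Object of class \code{"nuclear_family"} with a \code{design_tag}
#'   of \code{"trio"} or \code{"sibship"}.
#' @export
nuclear_family <- function(family_id, father = NULL, mother = NULL,
                           offspring, traits) {
  offspring <- matrix(as.numeric(offspring), nrow = NROW(offspring))
  stopifnot(nrow(offspring) >= 1L, length(traits) == nrow(offspring))
  has_f <- !is.null(father); has_m <- !is.null(mother)
  if (xor(has_f, has_m))
    stop("unsupported configuration: family ", family_id,
         " has exactly one typed parent")
  tag <- if (has_f) "trio" else "sibship"
  if (has_f)
    stopifnot(length(father) == ncol(offspring),
              length(mother) == ncol(offspring))
  structure(list(family_id = as.character(family_id),
                 father_genotypes = if (has_f) as.numeric(father),
                 mother_genotypes = if (has_m) as.numeric(mother),
                 offspring_genotypes = offspring,
                 offspring_traits = as.numeric(traits),
                 design_tag = tag),
            class = "nuclear_family")
}

#' Decompose a pedigree dataset into nuclear families
#'
#' Offspring with both parents present in the file form trio-like units (one
#' per father/mother pair, grouping full siblings); individuals whose parent
#' ids are both "0" and who are not themselves referenced as parents are
#' grouped by family id into a sibship without parental genotypes.
#' Individuals acting only as parents carry no trait.  A family containing
#' an offspring with exactly one known parent is rejected: conditioning on
#' partial parental information is not supported.
#'
#' @param dataset A \code{\link{pedigree_dataset}}.
#' @return List of \code{\link{nuclear_family}} objects.
#' @export
extract_nuclear_families <- function(dataset) {
  stopifnot(inherits(dataset, "pedigree_dataset"))
  ind <- dataset$individuals
  G <- dataset$genotypes
  key <- paste(ind$family_id, ind$individual_id)
  parent_keys <- unique(c(paste(ind$family_id, ind$father_id),
                          paste(ind$family_id, ind$mother_id)))
  is_parent <- key %in% parent_keys
  has_both <- ind$father_id != "0" & ind$mother_id != "0"
  has_one <- xor(ind$father_id != "0", ind$mother_id != "0")
  if (any(has_one))
    stop("unsupported configuration: individual ",
         ind$individual_id[has_one][1L], " in family ",
         ind$family_id[has_one][1L], " has exactly one known parent")

  out <- list()
  # trio-like units: group offspring by (family, father, mother)
  if (any(has_both)) {
    grp <- split(which(has_both),
                 paste(ind$family_id, ind$father_id, ind$mother_id)[has_both])
    for (rows in grp) {
      fid <- ind$family_id[rows[1L]]
      fa <- which(ind$family_id == fid &
                  ind$individual_id == ind$father_id[rows[1L]])
      mo <- which(ind$family_id == fid &
                  ind$individual_id == ind$mother_id[rows[1L]])
      out[[length(out) + 1L]] <- nuclear_family(
        fid, father = G[fa, ], mother = G[mo, ],
        offspring = G[rows, , drop = FALSE],
        traits = ind$phenotype[rows])
    }
  }
  # sibships without parents: unreferenced founders grouped by family
  sib <- !has_both & !is_parent
  if (any(sib)) {
    for (rows in split(which(sib), ind$family_id[sib])) {
      out[[length(out) + 1L]] <- nuclear_family(
        ind$family_id[rows[1L]],
        offspring = G[rows, , drop = FALSE],
        traits = ind$phenotype[rows])
    }
  }
  out
}
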