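# Inheritance cubes: genetic/mating outcome rules for wild-type and the four
# intervention systems, consumed by the population model.

WILD <- "WW"
SEXES <- c("f", "m")

#' Genotype-sex class labels for a genotype set
#'
#' Classes are labelled `"<genotype>:<sex>"` with sex `f` or `m`; every stage
#' matrix in the population model is indexed by these labels.
#'
#' @param genotypes character vector of genotype labels.
#' @return character vector of class labels, females first.
#' @keywords internal
class_labels <- function(genotypes) {
  as.vector(outer(genotypes, SEXES, paste, sep = ":"))
}

class_genotype <- function(classes) sub(":(f|m)$", "", classes)
class_sex <- function(classes) sub("^.*:", "", classes)

# Offspring distribution over genotype:sex classes for a single autosomal
# transgene locus; genotype labels count transgene copies: WW=0, RW=1, RR=2.
transgene_offspring <- function(mother_g, father_g, classes) {
  copies <- c(WW = 0, RW = 1, RR = 2)
  pm <- copies[[mother_g]] / 2
  pf <- copies[[father_g]] / 2
  # probability the offspring carries 0/1/2 transgene copies
  pg <- c(
    WW = (1 - pm) * (1 - pf),
    RW = pm * (1 - pf) + (1 - pm) * pf,
    RR = pm * pf
  )
  probs <- stats::setNames(numeric(length(classes)), classes)
  for (g in names(pg)) {
    if (pg[[g]] == 0) next
    probs[paste(g, SEXES, sep = ":")] <- pg[[g]] / 2
  }
  probs
}

# 1:1 wild-type Mendelian identity cross.
wild_offspring <- function(classes) {
  probs <- stats::setNames(numeric(length(classes)), classes)
  probs[paste(WILD, SEXES, sep = ":")] <- 0.5
  probs
}

#' Build an intervention cube
#'
#' Constructs a validated inheritance cube for one of the built-in systems:
#'
#' * `wild` — wild type only; Mendelian identity cross at a 1:1 sex ratio.
#' * `pgsit` — eggs of genotype `PG` are released; `PG` females die before
#'   pupation (`larva_exit`), `PG` males emerge sterile (all their matings
#'   yield no viable eggs) with mating competitiveness `c = 0.78`.
#' * `ridl` — homozygous `RR` adult males are released (`c = 0.05`); all their
#'   offspring (`RW`, both sexes) die at `pupa_exit`, so doomed larvae consume
#'   larval resources.
#' * `fsridl` — homozygous `RR` eggs are released; transgene-bearing females
#'   (`RR`, `RW`) die at `larva_exit` while carrier males are fertile with
#'   Mendelian transmission (`c = 0.05`).
#' * `iit` — Wolbachia-infected `II` adult males are released (`c = 1`); all
#'   matings involving them are incompatible (no viable eggs) and their adult
#'   mortality hazard is doubled (`omega = 2`), modeling the roughly halved
#'   longevity of irradiated infected males.
#'
#' Fitness multipliers are genotype-linked, so by default wild-born fsRIDL
#' carrier (`RW`) males inherit the released males' competitiveness; set
#' `released_only_fitness = TRUE` to treat the fitness cost as a rearing
#' effect confined to the released `RR` genotype.
#'
#' @param system one of `"wild"`, `"pgsit"`, `"ridl"`, `"fsridl"`, `"iit"`.
#' @param c_male optional override of the released-male mating
#'   competitiveness (a non-negative multiplier; wild-type males are fixed
#'   at 1).
#' @param omega optional override of the released genotype's adult mortality
#'   hazard multiplier (>= 1; wild type is fixed at 1).
#' @param death_stage named character vector of overrides, names being
#'   genotype:sex class labels and values in
#'   `c("none", "egg", "larva_exit", "pupa_exit")`.
#' @param release_stage optional override of the release stage, `"egg"` or
#'   `"adult_male"`.
#' @param released_only_fitness logical; see Details.
#' @return an object of class `intervention_cube`.
#' @examples
#' cube <- build_cube("pgsit")
#' offspring_distribution(cube, "WW", "PG")$viable_egg_fraction  # 0
#' @export
build_cube <- function(system = c("wild", "pgsit", "ridl", "fsridl", "iit"),
                       c_male = NULL, omega = NULL, death_stage = NULL,
                       release_stage = NULL, released_only_fitness = FALSE) {
  system <- match.arg(system)

  genotypes <- switch(system,
    wild = WILD,
    pgsit = c(WILD, "PG"),
    ridl = c(WILD, "RR", "RW"),
    fsridl = c(WILD, "RR", "RW"),
    iit = c(WILD, "II")
  )
  classes <- class_labels(genotypes)
  ng <- length(genotypes)

  cross_probs <- array(0, dim = c(length(classes), ng, ng),
                       dimnames = list(class = classes, mother = genotypes,
                                       father = genotypes))
  vef <- matrix(1, ng, ng, dimnames = list(mother = genotypes,
                                           father = genotypes))

  for (mg in genotypes) {
    for (fg in genotypes) {
      probs <- switch(system,
        wild = wild_offspring(classes),
        pgsit = {
          if (fg == "PG" || mg == "PG") {
            # sterile-sired (or, defensively, sterile-mothered) matings yield
            # no viable egg input
            vef[mg, fg] <- 0
            stats::setNames(numeric(length(classes)), classes)
          } else {
            wild_offspring(classes)
          }
        },
        ridl = transgene_offspring(mg, fg, classes),
        fsridl = transgene_offspring(mg, fg, classes),
        iit = {
          if (fg == "II" || mg == "II") {
            vef[mg, fg] <- 0
            stats::setNames(numeric(length(classes)), classes)
          } else {
            wild_offspring(classes)
          }
        }
      )
      cross_probs[, mg, fg] <- probs
    }
  }

  ds <- stats::setNames(rep("none", length(classes)), classes)
  switch(system,
    pgsit = {
      ds["PG:f"] <- "larva_exit"
    },
    ridl = {
      ds[c("RW:f", "RW:m")] <- "pupa_exit"
      ds["RR:f"] <- "pupa_exit"  # defensively: homozygous offspring doomed too
    },
    fsridl = {
      ds[c("RR:f", "RW:f")] <- "larva_exit"
    }
  )
  if (system == "wild") ds <- ds  # no doomed classes

  mating_c <- stats::setNames(rep(1, ng), genotypes)
  omega_g <- stats::setNames(rep(1, ng), genotypes)
  fertile_male <- stats::setNames(rep(TRUE, ng), genotypes)

  release_genotype <- switch(system, wild = WILD, pgsit = "PG",
                             ridl = "RR", fsridl = "RR", iit = "II")
  rel_stage <- switch(system,
    wild = "adult_male", pgsit = "egg", ridl = "adult_male",
    fsridl = "egg", iit = "adult_male"
  )

  switch(system,
    pgsit = {
      mating_c["PG"] <- 0.78
      fertile_male["PG"] <- FALSE
    },
    ridl = {
      mating_c[c("RR", "RW")] <- 0.05
      # RR males sire only doomed offspring; no fertile transgenic lineage
      fertile_male[c("RR", "RW")] <- FALSE
    },
    fsridl = {
      mating_c[c("RR", "RW")] <- if (released_only_fitness) c(0.05, 1) else 0.05
      fertile_male[c("RR", "RW")] <- TRUE
    },
    iit = {
      omega_g["II"] <- 2
      fertile_male["II"] <- FALSE
    }
  )

  if (!is.null(c_male)) {
    stopifnot(is.numeric(c_male), c_male >= 0)
    if (system == "wild") stop("cannot override wild-type male competitiveness")
    tg <- setdiff(genotypes, WILD)
    if (system == "fsridl" && released_only_fitness) tg <- "RR"
    mating_c[tg] <- c_male
  }
  if (!is.null(omega)) {
    stopifnot(is.numeric(omega), omega >= 1)
    if (system == "wild") stop("cannot override wild-type mortality multiplier")
    omega_g[setdiff(genotypes, WILD)] <- omega
  }
  if (!is.null(death_stage)) {
    bad <- setdiff(names(death_stage), classes)
    if (length(bad)) {
      stop("death_stage override references undeclared classes: ",
           paste(bad, collapse = ", "))
    }
    stopifnot(all(death_stage %in% c("none", "egg", "larva_exit", "pupa_exit")))
    ds[names(death_stage)] <- death_stage
  }
  if (!is.null(release_stage)) {
    rel_stage <- match.arg(release_stage, c("egg", "adult_male"))
  }

  cube <- structure(
    list(
      name = system,
      genotypes = genotypes,
      classes = classes,
      cross_probs = cross_probs,
      vef = vef,
      death_stage = ds,
      mating_c = mating_c,
      omega = omega_g,
      fertile_male = fertile_male,
      release_stage = rel_stage,
      release_genotype = release_genotype,
      released_only_fitness = released_only_fitness
    ),
    class = "intervention_cube"
  )
  viol <- validate_cube(cube)
  if (length(viol)) {
    stop("built cube fails validation:\n  ", paste(viol, collapse = "\n  "))
  }
  cube
}

#' Look up the offspring distribution of a cross
#'
#' @param cube an `intervention_cube`.
#' @param mother_g,father_g genotype labels present in the cube.
#' @return a list with `entries` (named probability vector over genotype:sex
#'   classes; empty when no viable eggs result) and `viable_egg_fraction`.
#' @export
offspring_distribution <- function(cube, mother_g, father_g) {
  stopifnot(inherits(cube, "intervention_cube"))
  if (!mother_g %in% cube$genotypes || !father_g %in% cube$genotypes) {
    stop("unknown genotype pair (", mother_g, ", ", father_g, ") for cube '",
         cube$name, "'")
  }
  p <- cube$cross_probs[, mother_g, father_g]
  v <- cube$vef[mother_g, father_g]
  list(entries = if (v > 0) p[p > 0] else stats::setNames(numeric(0), character(0)),
       viable_egg_fraction = v)
}

#' Validate an intervention cube
#'
#' Checks every type invariant: cross probabilities non-negative and summing
#' to 1 (or empty with `viable_egg_fraction = 0`), all referenced classes
#' declared, wild-type fitness fixed at 1, and a Mendelian wild x wild cross.
#' Violations are returned as data, not raised as errors.
#'
#' @param cube an `intervention_cube`.
#' @return character vector of violation messages; empty if the cube is valid.
#' @export
validate_cube <- function(cube) {
  viol <- character(0)
  g <- cube$genotypes
  cls <- cube$classes
  if (!WILD %in% g) viol <- c(viol, "genotype set lacks wild type 'WW'")
  if (!setequal(cls, class_labels(g))) {
    viol <- c(viol, "classes do not match genotype x sex labels")
  }
  for (mg in g) {
    for (fg in g) {
      p <- cube$cross_probs[, mg, fg]
      v <- cube$vef[mg, fg]
      if (any(p < 0)) {
        viol <- c(viol, sprintf("cross (%s, %s): negative probability", mg, fg))
      }
      if (v > 0 && abs(sum(p) - 1) > 1e-12) {
        viol <- c(viol, sprintf(
          "cross (%s, %s): probabilities sum to %.6g, not 1", mg, fg, sum(p)))
      }
      if (v == 0 && sum(p) != 0) {
        viol <- c(viol, sprintf(
          "cross (%s, %s): inviable cross carries offspring mass", mg, fg))
      }
      if (v < 0 || v > 1) {
        viol <- c(viol, sprintf("cross (%s, %s): viable_egg_fraction %.3g not in [0,1]",
                                mg, fg, v))
      }
    }
  }
  pw <- cube$cross_probs[, WILD, WILD]
  expected <- wild_offspring(cls)
  if (cube$vef[WILD, WILD] != 1 || any(abs(pw - expected) > 1e-12)) {
    viol <- c(viol, "wild x wild cross is not Mendelian 1:1 wild offspring")
  }
  if (cube$mating_c[[WILD]] != 1) {
    viol <- c(viol, "wild-type male mating competitiveness != 1")
  }
  if (cube$omega[[WILD]] != 1) {
    viol <- c(viol, "wild-type mortality multiplier != 1")
  }
  if (any(cube$mating_c < 0)) viol <- c(viol, "negative mating competitiveness")
  if (any(cube$omega < 1)) viol <- c(viol, "mortality multiplier below 1")
  if (!all(cube$death_stage %in% c("none", "egg", "larva_exit", "pupa_exit"))) {
    viol <- c(viol, "unknown death_stage value")
  }
  viol
}

#' Serialize a cube to JSON
#'
#' The JSON document stores the genotype list, the full cross table (offspring
#' probabilities and viable-egg fraction per mother/father pair), and the
#' per-class / per-genotype attributes; [cube_from_json()] restores it
#' losslessly.
#'
#' @param cube an `intervention_cube`.
#' @param path optional file path; if `NULL` the JSON string is returned.
#' @return invisibly, the JSON string.
#' @export
cube_to_json <- function(cube, path = NULL) {
  stopifnot(inherits(cube, "intervention_cube"))
  cross <- list()
  for (mg in cube$genotypes) {
    cross[[mg]] <- list()
    for (fg in cube$genotypes) {
      cross[[mg]][[fg]] <- list(
        probs = as.list(cube$cross_probs[, mg, fg]),
        viable_egg_fraction = cube$vef[mg, fg]
      )
    }
  }
  doc <- list(
    name = cube$name,
    genotypes = cube$genotypes,
    classes = cube$classes,
    cross = cross,
    death_stage = as.list(cube$death_stage),
    mating_c = as.list(cube$mating_c),
    omega = as.list(cube$omega),
    fertile_male = as.list(cube$fertile_male),
    release_stage = cube$release_stage,
    release_genotype = cube$release_genotype,
    released_only_fitness = cube$released_only_fitness
  )
  json <- jsonlite::toJSON(doc, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  if (!is.null(path)) writeLines(json, path)
  invisible(json)
}

#' Restore a cube from JSON
#'
#' @param json a JSON string, or a path to a JSON file.
#' @return an `intervention_cube`.
#' @export
cube_from_json <- function(json) {
  if (length(json) == 1 && file.exists(json)) json <- paste(readLines(json), collapse = "\n")
  doc <- jsonlite::fromJSON(json, simplifyVector = FALSE)
  genotypes <- unlist(doc$genotypes)
  classes <- unlist(doc$classes)
  ng <- length(genotypes)
  cross_probs <- array(0, dim = c(length(classes), ng, ng),
                       dimnames = list(class = classes, mother = genotypes,
                                       father = genotypes))
  vef <- matrix(1, ng, ng, dimnames = list(mother = genotypes, father = genotypes))
  for (mg in genotypes) {
    for (fg in genotypes) {
      entry <- doc$cross[[mg]][[fg]]
      cross_probs[, mg, fg] <- unlist(entry$probs)[classes]
      vef[mg, fg] <- entry$viable_egg_fraction
    }
  }
  structure(
    list(
      name = doc$name,
      genotypes = genotypes,
      classes = classes,
      cross_probs = cross_probs,
      vef = vef,
      death_stage = unlist(doc$death_stage)[classes],
      mating_c = unlist(doc$mating_c)[genotypes],
      omega = unlist(doc$omega)[genotypes],
      fertile_male = unlist(doc$fertile_male)[genotypes],
      release_stage = doc$release_stage,
      release_genotype = doc$release_genotype,
      released_only_fitness = isTRUE(doc$released_only_fitness)
    ),
    class = "intervention_cube"
  )
}

#' @export
print.intervention_cube <- function(x, ...) {
  cat("Intervention cube '", x$name, "'\n", sep = "")
  cat("  genotypes:", paste(x$genotypes, collapse = ", "), "\n")
  cat("  release:", x$release_genotype, "at stage", x$release_stage, "\n")
  cat("  male competitiveness:",
      paste(sprintf("%s=%.3g", names(x$mating_c), x$mating_c), collapse = ", "), "\n")
  cat("  mortality multiplier:",
      paste(sprintf("%s=%.3g", names(x$omega), x$omega), collapse = ", "), "\n")
  doomed <- x$death_stage[x$death_stage != "none"]
  if (length(doomed)) {
    cat("  doomed classes:",
        paste(sprintf("%s@%s", names(doomed), doomed), collapse = ", "), "\n")
  }
  invisible(x)
}
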