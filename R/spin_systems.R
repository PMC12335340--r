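## Spin-system prior knowledge: chemical shifts, equivalence groups,
## uncoupled subsystems and scalar couplings, loaded from the plain-text
## constants tables shipped with the package.

constants_path <- function(file) {
  system.file("extdata", file, package = "mrsiglx", mustWork = TRUE)
}

read_constants_tables <- function(shifts_file = NULL, j_file = NULL) {
  shifts_file <- shifts_file %||% constants_path("spin_systems.tsv")
  j_file <- j_file %||% constants_path("jcouplings.tsv")
  shifts <- utils::read.delim(shifts_file, comment.char = "#",
                              stringsAsFactors = FALSE)
  jc <- utils::read.delim(j_file, comment.char = "#",
                          stringsAsFactors = FALSE)
  list(shifts = shifts, j = jc)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' List metabolites available in the constants table
#' @param tables Optional list as returned by the internal table reader;
#'   defaults to the shipped tables.
#' @return Character vector of metabolite names.
#' @export
available_metabolites <- function(tables = NULL) {
  tables <- tables %||% read_constants_tables()
  unique(tables$shifts$metabolite)
}

#' Load a metabolite spin system from the constants tables
#'
#' Builds a `spin_system` object holding the chemical shifts (ppm), the
#' symmetric J-coupling matrix (Hz), the partition of protons into
#' magnetically equivalent groups and the partition into mutually
#' uncoupled subsystems.
#'
#' @param name Metabolite identifier, e.g. `"Glu"`, `"Gln"`, `"Cr"`.
#' @param tables Optional constants tables (for testing with custom
#'   systems); defaults to the shipped tables.
#' @return An object of class `spin_system` with fields `name`, `protons`,
#'   `shifts`, `J`, `groups`, `subsystems`.
#' @export
load_spin_system <- function(name, tables = NULL) {
  tables <- tables %||% read_constants_tables()
  sh <- tables$shifts[tables$shifts$metabolite == name, , drop = FALSE]
  if (nrow(sh) == 0)
    stop("unknown metabolite: '", name, "'")
  protons <- sh$proton
  if (anyDuplicated(protons))
    stop("duplicated proton labels for ", name)
  n <- length(protons)
  J <- matrix(0, n, n, dimnames = list(protons, protons))
  jc <- tables$j[tables$j$metabolite == name, , drop = FALSE]
  for (k in seq_len(nrow(jc))) {
    i <- match(jc$proton_i[k], protons)
    j <- match(jc$proton_j[k], protons)
    if (is.na(i) || is.na(j))
      stop("J-coupling refers to unknown proton in ", name)
    J[i, j] <- J[j, i] <- jc$j_hz[k]
  }
  sys <- structure(list(name = name, protons = protons,
                        shifts = stats::setNames(sh$shift_ppm, protons),
                        J = J,
                        groups = stats::setNames(sh$group, protons),
                        subsystems = stats::setNames(sh$subsystem, protons)),
                   class = "spin_system")
  validate_spin_system(sys)
  sys
}

#' Validate the invariants of a spin system
#'
#' Checks that J is symmetric with zero diagonal, that protons in different
#' subsystems are uncoupled, and that shifts within an equivalence group
#' are identical.
#'
#' @param sys A `spin_system`.
#' @return The system, invisibly; errors on violation.
#' @export
validate_spin_system <- function(sys) {
  J <- sys$J
  if (!isSymmetric(unname(J), tol = 0))
    stop("J matrix for ", sys$name, " is not symmetric")
  if (any(diag(J) != 0))
    stop("J matrix for ", sys$name, " has nonzero diagonal")
  sub <- sys$subsystems
  cross <- outer(sub, sub, "!=") & (J != 0)
  if (any(cross))
    stop("nonzero J between different subsystems in ", sys$name)
  for (g in unique(sys$groups)) {
    s <- sys$shifts[sys$groups == g]
    if (length(unique(s)) != 1)
      stop("unequal shifts within equivalence group '", g, "' of ", sys$name)
  }
  invisible(sys)
}

#' @export
print.spin_system <- function(x, ...) {
  cat("<spin_system>", x$name, "-", length(x$protons), "protons,",
      length(unique(x$subsystems)), "uncoupled subsystem(s)\n")
  cat("  shifts (ppm):", paste(format(x$shifts, digits = 5), collapse = " "),
      "\n")
  ncpl <- sum(x$J[upper.tri(x$J)] != 0)
  cat(" ", ncpl, "nonzero J coupling(s)\n")
  invisible(x)
}

## Split a spin system into connected components of the J-coupling graph
## within each declared subsystem.  Each component evolves independently and
## is simulated on its own (small) Hilbert space.
spin_components <- function(sys) {
  n <- length(sys$protons)
  adj <- (sys$J != 0)
  comp <- seq_len(n)
  repeat {
    changed <- FALSE
    for (i in seq_len(n)) for (j in seq_len(n)) {
      if (adj[i, j] && comp[j] != comp[i]) {
        m <- min(comp[i], comp[j]); comp[comp == comp[i] | comp == comp[j]] <- m
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  lapply(unique(comp), function(cid) which(comp == cid))
}
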