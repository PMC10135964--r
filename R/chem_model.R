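#' Define an equilibrium species
#'
#' A species is a 1:1 ligand complex (or the free ligand itself) assembled
#' from the fully deprotonated ligand, protons and metal ions:
#' \eqn{h\,H^+ + k\,K^+ + m\,Mg^{2+} + l\,L \rightleftharpoons H_hK_kMg_mL_l},
#' with cumulative formation constant \eqn{\log_{10}\beta} on the molar
#' concentration scale (constant ionic medium; no activity corrections).
#'
#' @param id Short unique label, e.g. `"MgK3H3L"`.
#' @param n_h,n_k,n_mg Non-negative integer counts of bound H+, K+ and Mg2+.
#' @param log_beta Cumulative formation constant (log10), referenced to the
#'   fully deprotonated free ligand and free ions.  The free ligand has
#'   `log_beta = 0` by convention.
#' @param n_l Ligand count; 1 for every real species (0 is reserved for the
#'   implicit free-ion "species" and never stored in a model).
#' @param display Formatted name, e.g. `"[MgK3(H3L)]6-"`.  Derived from the
#'   stoichiometry when omitted.
#' @param conformer One of `"axial"`, `"equatorial"`, `"unspecified"` — a data
#'   annotation only, never inferred.
#' @return A `species_def` list.
#' @seealso [chem_model()], [species_charge()]
#' @export
species_def <- function(id, n_h = 0L, n_k = 0L, n_mg = 0L, log_beta = 0,
                        n_l = 1L, display = NULL,
                        conformer = c("unspecified", "axial", "equatorial")) {
  conformer <- match.arg(conformer)
  n_h <- as.integer(n_h); n_k <- as.integer(n_k)
  n_mg <- as.integer(n_mg); n_l <- as.integer(n_l)
  if (any(c(n_h, n_k, n_mg) < 0L)) {
    stop("stoichiometric coefficients must be non-negative", call. = FALSE)
  }
  if (!n_l %in% c(0L, 1L)) {
    stop("n_l must be 0 or 1 (no polynuclear species)", call. = FALSE)
  }
  if (!is.finite(log_beta)) stop("log_beta must be finite", call. = FALSE)
  if (is.null(display)) display <- default_display(n_h, n_k, n_mg)
  structure(
    list(id = as.character(id), display = display, n_h = n_h, n_k = n_k,
         n_mg = n_mg, n_l = n_l, log_beta = as.numeric(log_beta),
         conformer = conformer),
    class = "species_def")
}

default_display <- function(n_h, n_k, n_mg) {
  core <- if (n_h > 0) sprintf("(H%sL)", if (n_h > 1) n_h else "") else "L"
  pre <- paste0(if (n_mg > 0) sprintf("Mg%s", if (n_mg > 1) n_mg else "") else "",
                if (n_k > 0) sprintf("K%s", if (n_k > 1) n_k else "") else "")
  if (nzchar(pre)) sprintf("[%s%s]", pre, core) else core
}

#' Net charge of a species from its stoichiometry
#'
#' `charge = base_charge * n_l + n_h + n_k + 2 * n_mg`; reproduces every
#' superscript of the packaged models (e.g. `[K5(HL)]`: -14 + 1 + 5 = -8).
#'
#' @param species A [species_def()].
#' @param base_charge Charge of the fully deprotonated ligand (-14 for InsP8,
#'   -13 for 5PCP-InsP5, -12 for InsP6).
#' @return Integer net charge.
#' @export
species_charge <- function(species, base_charge) {
  stopifnot(inherits(species, "species_def"))
  as.integer(base_charge * species$n_l + species$n_h + species$n_k +
               2L * species$n_mg)
}

#' Assemble and validate a chemical model
#'
#' @param ligand_name Ligand label, e.g. `"InsP8"`.
#' @param base_charge Integer charge of the fully deprotonated ligand.
#' @param species List of [species_def()]s; must contain exactly one
#'   free-ligand entry (`n_h = n_k = n_mg = 0`, `n_l = 1`).
#' @param medium Free-text metadata (ionic strength, temperature).
#' @return A `chem_model` object.  `$tab` holds the species table as a
#'   data.frame (one row per species) used by the solver.
#' @export
chem_model <- function(ligand_name, base_charge, species, medium = "") {
  if (inherits(species, "species_def")) species <- list(species)
  stopifnot(length(species) >= 1L,
            all(vapply(species, inherits, TRUE, "species_def")))
  ids <- vapply(species, `[[`, "", "id")
  if (anyDuplicated(ids)) {
    stop("duplicate species id: ", ids[duplicated(ids)][1L], call. = FALSE)
  }
  tab <- data.frame(
    id = ids,
    display = vapply(species, `[[`, "", "display"),
    n_h = vapply(species, `[[`, 0L, "n_h"),
    n_k = vapply(species, `[[`, 0L, "n_k"),
    n_mg = vapply(species, `[[`, 0L, "n_mg"),
    n_l = vapply(species, `[[`, 0L, "n_l"),
    log_beta = vapply(species, `[[`, 0, "log_beta"),
    conformer = vapply(species, `[[`, "", "conformer"),
    stringsAsFactors = FALSE)
  tab$charge <- as.integer(base_charge * tab$n_l + tab$n_h + tab$n_k +
                             2L * tab$n_mg)
  free <- tab$n_h == 0L & tab$n_k == 0L & tab$n_mg == 0L & tab$n_l == 1L
  if (sum(free) != 1L) {
    stop("model must contain exactly one free-ligand species", call. = FALSE)
  }
  if (abs(tab$log_beta[free]) > 0) {
    stop("free ligand must have log_beta = 0", call. = FALSE)
  }
  if (any(tab$n_l == 0L)) {
    stop("free ions are solver inputs, not model species", call. = FALSE)
  }
  m <- structure(
    list(ligand_name = ligand_name, base_charge = as.integer(base_charge),
         species = species, medium = medium, tab = tab),
    class = "chem_model")
  # stepwise protonation constants must exist and be positive
  steps <- stepwise_log_k(m)
  if (length(steps) && any(!is.finite(steps) | steps <= 0)) {
    stop("cumulative protonation constants imply a non-positive stepwise log K",
         call. = FALSE)
  }
  m
}

#' @export
print.chem_model <- function(x, ...) {
  cat(sprintf("<chem_model> %s (L%+d), %d species; %s\n",
              x$ligand_name, x$base_charge, nrow(x$tab), x$medium))
  print(x$tab[, c("id", "display", "n_h", "n_k", "n_mg", "log_beta",
                  "charge", "conformer")], row.names = FALSE)
  invisible(x)
}

#' Stepwise protonation constants of the H+-only ladder
#'
#' Differences of consecutive cumulative constants of HnL species
#' (no metals): `log K_n = log beta(HnL) - log beta(H(n-1)L)`.
#'
#' @param model A [chem_model()].
#' @return Named numeric vector (`"K1"`, `"K2"`, ...), empty if the model has
#'   no protonated metal-free species.
#' @export
stepwise_log_k <- function(model) {
  tab <- model$tab
  h <- tab[tab$n_k == 0L & tab$n_mg == 0L & tab$n_l == 1L, ]
  h <- h[order(h$n_h), ]
  if (nrow(h) < 2L) return(numeric(0))
  if (!identical(h$n_h, seq_len(nrow(h)) - 1L)) {
    # ladder has gaps; report only defined consecutive steps
    keep <- which(diff(h$n_h) == 1L)
    if (!length(keep)) return(numeric(0))
    out <- h$log_beta[keep + 1L] - h$log_beta[keep]
    names(out) <- paste0("K", h$n_h[keep + 1L])
    return(out)
  }
  out <- diff(h$log_beta)
  names(out) <- paste0("K", h$n_h[-1L])
  out
}

#' Count species matching a stoichiometry predicate
#'
#' @param model A [chem_model()].
#' @param filter Function taking the species table (data.frame) and returning
#'   a logical vector, e.g. `function(s) s$n_k > 0 & s$n_mg == 0`.
#' @return Integer count.
#' @examples
#' m <- ipp_model("insp8")
#' count_species(m, function(s) s$n_k > 0 & s$n_mg == 0)  # 6 K+-only complexes
#' @export
count_species <- function(model, filter) {
  stopifnot(inherits(model, "chem_model"), is.function(filter))
  sum(filter(model$tab))
}

#' Restrict a model to a subset of species
#'
#' Convenience for building candidate models (e.g. the H+-only ladder from the
#' full K+/Mg2+ model) without re-entering constants.
#'
#' @param model A [chem_model()].
#' @param keep Logical vector over `model$tab` rows, character ids, or a
#'   predicate function on the species table.
#' @return A validated [chem_model()].
#' @export
subset_model <- function(model, keep) {
  if (is.function(keep)) keep <- keep(model$tab)
  if (is.character(keep)) keep <- model$tab$id %in% keep
  chem_model(model$ligand_name, model$base_charge,
             model$species[keep], model$medium)
}

# ---- model document I/O -----------------------------------------------------

#' Read a chemical-model document
#'
#' The document format is plain text: `#` comments, `key: value` header lines
#' (`ligand`, `base_charge`, `medium`), then a `species:` line followed by a
#' whitespace-separated table with header
#' `id display n_h n_k n_mg n_l log_beta conformer charge`.
#' The stored `charge` column is validated against the charge formula; a
#' mismatch is an error (it catches transcription slips).
#'
#' @param path Path to a `.model` file.
#' @return A validated [chem_model()].
#' @seealso [write_chem_model()], [ipp_model()]
#' @export
read_chem_model <- function(path) {
  if (!file.exists(path)) stop("no such model document: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  isp <- match("species:", lines)
  if (is.na(isp)) stop("model document has no 'species:' section", call. = FALSE)
  hdr <- lines[seq_len(isp - 1L)]
  kv <- regmatches(hdr, regexec("^([a-z_]+):\\s*(.*)$", hdr))
  keys <- vapply(kv, `[`, "", 2L)
  vals <- vapply(kv, `[`, "", 3L)
  need <- c("ligand", "base_charge")
  if (!all(need %in% keys)) {
    stop("model document missing header field(s): ",
         paste(setdiff(need, keys), collapse = ", "), call. = FALSE)
  }
  ligand <- vals[keys == "ligand"][1L]
  base_charge <- suppressWarnings(as.integer(vals[keys == "base_charge"][1L]))
  if (is.na(base_charge)) stop("base_charge is not an integer", call. = FALSE)
  medium <- if ("medium" %in% keys) vals[keys == "medium"][1L] else ""
  body <- lines[(isp + 1L):length(lines)]
  cols <- strsplit(body[1L], "\\s+")[[1L]]
  need_cols <- c("id", "n_h", "n_k", "n_mg", "log_beta")
  if (!all(need_cols %in% cols)) {
    stop("species table missing column(s): ",
         paste(setdiff(need_cols, cols), collapse = ", "), call. = FALSE)
  }
  sp <- vector("list", length(body) - 1L)
  for (i in seq_along(sp)) {
    f <- strsplit(body[i + 1L], "\\s+")[[1L]]
    if (length(f) != length(cols)) {
      stop(sprintf("species row %d has %d fields, expected %d",
                   i, length(f), length(cols)), call. = FALSE)
    }
    rec <- stats::setNames(as.list(f), cols)
    num <- function(key) {
      v <- suppressWarnings(as.numeric(rec[[key]]))
      if (is.na(v)) stop(sprintf("species row %d: non-numeric %s ('%s')",
                                 i, key, rec[[key]]), call. = FALSE)
      v
    }
    s <- species_def(
      id = rec$id, n_h = num("n_h"), n_k = num("n_k"), n_mg = num("n_mg"),
      n_l = if ("n_l" %in% cols) num("n_l") else 1L,
      log_beta = num("log_beta"),
      display = if ("display" %in% cols) rec$display else NULL,
      conformer = if ("conformer" %in% cols) rec$conformer else "unspecified")
    if ("charge" %in% cols) {
      stored <- as.integer(num("charge"))
      calc <- species_charge(s, base_charge)
      if (stored != calc) {
        stop(sprintf(
          "species '%s': stored charge %d contradicts stoichiometry (%d)",
          rec$id, stored, calc), call. = FALSE)
      }
    }
    sp[[i]] <- s
  }
  chem_model(ligand, base_charge, sp, medium)
}

#' Write a chemical-model document
#'
#' @param model A [chem_model()].
#' @param path Output path.
#' @return `path`, invisibly.  `read_chem_model(write_chem_model(m, p))`
#'   round-trips to an identical model.
#' @export
write_chem_model <- function(model, path) {
  stopifnot(inherits(model, "chem_model"))
  tab <- model$tab
  con <- file(path, "w"); on.exit(close(con))
  writeLines(c(sprintf("ligand: %s", model$ligand_name),
               sprintf("base_charge: %d", model$base_charge),
               sprintf("medium: %s", model$medium),
               "species:",
               paste("id", "display", "n_h", "n_k", "n_mg", "n_l",
                     "log_beta", "conformer", "charge")), con)
  writeLines(sprintf("%s %s %d %d %d %d %.10g %s %d",
                     tab$id, tab$display, tab$n_h, tab$n_k, tab$n_mg, tab$n_l,
                     tab$log_beta, tab$conformer, tab$charge), con)
  invisible(path)
}

#' Load a packaged chemical model
#'
#' Ships the published formation-constant sets (I = 0.15 M) as model
#' documents: `"insp8"` (1,5(PP)2-InsP4, L^14-; 22 degC, 31P NMR),
#' `"pcp_insp5"` (5PCP-InsP5, L^13-; 22 degC, 31P NMR) and `"insp6"`
#' (InsP6, L^12-; 37 degC, potentiometry).  Cumulative log beta values are
#' sums of the published stepwise constants; entries absent from the source
#' table are omitted.
#'
#' @param name One of `"insp8"`, `"pcp_insp5"`, `"insp6"`.
#' @return A [chem_model()].
#' @examples
#' ipp_model("insp8")
#' @export
ipp_model <- function(name = c("insp8", "pcp_insp5", "insp6")) {
  name <- match.arg(name)
  path <- system.file("extdata", "models", paste0(name, ".model"),
                      package = "ippspec", mustWork = TRUE)
  read_chem_model(path)
}

#' The H+-only protonation ladder of a packaged model
#'
#' @param model A [chem_model()] (defaults to the packaged InsP8 model).
#' @return The model restricted to metal-free species (free L + HnL ladder).
#' @export
protonation_model <- function(model = ipp_model("insp8")) {
  subset_model(model, function(s) s$n_k == 0L & s$n_mg == 0L)
}
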