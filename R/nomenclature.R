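#' @importFrom rlang .data
#' @importFrom tibble tibble as_tibble
NULL

# Recognized headgroup classes and their structural conventions.
# Slot counts include "0:0" placeholders as printed in shorthand names;
# canonical acyl counts are the number of *filled* chains a non-lyso species
# of that class carries (DG's three glycerol slots canonically include one
# empty slot, so its canonical acyl count is 2).
.LIPID_CLASSES <- c("PG", "PE", "PC", "PA", "CL", "DG", "TG", "Cer", "HexCer")

.SLOT_COUNT <- c(
  PG = 2L, PE = 2L, PC = 2L, PA = 2L, CL = 4L,
  DG = 3L, TG = 3L, Cer = 2L, HexCer = 2L
)

.CANONICAL_ACYL <- c(
  PG = 2L, PE = 2L, PC = 2L, PA = 2L, CL = 4L,
  DG = 2L, TG = 3L, Cer = 2L, HexCer = 2L
)

# Headgroup net charge at physiological pH. PA is chemically anionic and is
# recorded as such on every species; charge-composition profiles offer a
# basis that excludes PA (see charge_profile()).
.CHARGE_MAP <- c(
  PG = "anionic", CL = "anionic", PA = "anionic",
  PC = "zwitterionic", PE = "zwitterionic",
  DG = "neutral", TG = "neutral", Cer = "neutral", HexCer = "neutral"
)

# Default ESI ionization mode in which each class is detected.
.MODE_MAP <- c(
  PG = "negative", PE = "negative", PA = "negative", CL = "negative",
  PC = "positive", DG = "positive", TG = "positive",
  Cer = "positive", HexCer = "positive"
)

#' Shorthand names of lipid species observed in shale-bacterium lipidomes
#'
#' A reference corpus of intact-polar-lipid species names reported for
#' *Halanaerobium congolense* WG10 cultures and mixed shale-produced-fluid
#' consortia. The set exercises every feature of the shorthand grammar:
#' full-chain and sum-composition annotations, lyso species (a `0:0` slot),
#' four-chain cardiolipins, sphingoid (`d`-prefixed) bases, chromatographic
#' isomer suffixes (`_A`, `_B`) and ambiguous dual annotations joined by `/`.
#'
#' @return Character vector of species names.
#' @export
#' @examples
#' parse_lipid_name(reference_species_names()[1])
reference_species_names <- function() {
  c(
    "PG(18:1/0:0)_A",
    "PG(18:1/0:0)_B",
    "PE(16:0/18:1)/PE(16:1/18:0)",
    "PG(35:1)",
    "PG(14:1/15:1)",
    "PC(18:0/19:1)",
    "HexCer(d18:2/16:1)_B",
    "PG(12:0/13:0)",
    "PC(16:0/18:0)",
    "PE(17:1/18:0)/PE(16:0/19:1)",
    "DG(32:1)",
    "PE(16:0/17:1)",
    "PE(19:1/19:1)",
    "DG(16:1/0:0/16:1)",
    "PE(17:1/19:1)",
    "PC(16:1/0:0)_B",
    "CL(17:1/16:0/16:1/17:1)",
    "DG(14:0/16:1/0:0)_B/DG(14:1/16:0/0:0)",
    "DG(15:1/16:1/0:0)",
    "DG(14:0/16:1/0:0)_A",
    "PG(14:0/0:0)_B",
    "CL(14:0/16:1/16:1/16:1)",
    "PG(16:0/16:1)_B",
    "PG(14:1/14:1)"
  )
}

# Split a name on "/" characters that sit at parenthesis depth zero;
# these separate alternative whole-species annotations, not chains.
.split_top_level <- function(name) {
  chars <- strsplit(name, "", fixed = TRUE)[[1]]
  depth <- 0L
  cuts <- integer(0)
  for (i in seq_along(chars)) {
    if (chars[i] == "(") depth <- depth + 1L
    else if (chars[i] == ")") depth <- depth - 1L
    else if (chars[i] == "/" && depth == 0L) cuts <- c(cuts, i)
  }
  if (length(cuts) == 0L) return(name)
  starts <- c(1L, cuts + 1L)
  ends <- c(cuts - 1L, length(chars))
  vapply(seq_along(starts), function(k) {
    paste(chars[starts[k]:ends[k]], collapse = "")
  }, character(1))
}

# Parse one "C:D" (optionally "dC:D") term. `offset` is the 1-based position
# of the term's first character in the full raw name, used for error messages.
.parse_chain_term <- function(term, raw_name, offset) {
  m <- regexec("^(d?)([0-9]+):([0-9]+)$", term)[[1]]
  if (m[1] == -1L) {
    stop(
      sprintf(
        "malformed composition term %s at character %d of %s",
        dQuote(term, FALSE), offset, dQuote(raw_name, FALSE)
      ),
      call. = FALSE
    )
  }
  parts <- regmatches(term, regexec("^(d?)([0-9]+):([0-9]+)$", term))[[1]]
  list(
    carbons = as.integer(parts[3]),
    double_bonds = as.integer(parts[4]),
    sphingoid = identical(parts[2], "d")
  )
}

.parse_single_annotation <- function(text, raw_name) {
  stripped <- gsub(" ", "", text, fixed = TRUE)
  m <- regexec("^([A-Za-z]+)\\(([^()]*)\\)(?:_([A-Za-z0-9]+))?$", stripped)
  parts <- regmatches(stripped, m)[[1]]
  if (length(parts) == 0L) {
    stop(
      sprintf("cannot parse lipid name %s", dQuote(text, FALSE)),
      call. = FALSE
    )
  }
  cls <- parts[2]
  if (!cls %in% .LIPID_CLASSES) {
    stop(
      sprintf("unknown lipid class token %s in %s",
              dQuote(cls, FALSE), dQuote(text, FALSE)),
      call. = FALSE
    )
  }
  composition <- parts[3]
  isomer <- if (is.na(parts[4]) || parts[4] == "") NULL else parts[4]

  terms <- strsplit(composition, "/", fixed = TRUE)[[1]]
  if (length(terms) == 0L || any(terms == "")) {
    stop(
      sprintf("empty composition term in %s", dQuote(text, FALSE)),
      call. = FALSE
    )
  }
  # character offset of each term inside the stripped annotation
  base <- nchar(cls) + 2L # class token + "("
  offsets <- base + c(0L, cumsum(nchar(terms) + 1L))[seq_along(terms)]
  chains <- lapply(seq_along(terms), function(i) {
    .parse_chain_term(terms[i], raw_name, offsets[i])
  })

  slot <- .SLOT_COUNT[[cls]]
  if (length(chains) == 1L && slot > 1L) {
    # single term for a multi-slot class: sum composition
    comp <- chains[[1]]
    if (comp$sphingoid) {
      stop(
        sprintf("sphingoid marker on a sum composition in %s",
                dQuote(text, FALSE)),
        call. = FALSE
      )
    }
    return(.new_lipid_species(
      raw_name = text, lipid_class = cls,
      chains = data.frame(
        carbons = integer(0), double_bonds = integer(0), sphingoid = logical(0)
      ),
      resolution = "sum_composition",
      isomer_label = isomer,
      total_carbons = comp$carbons,
      total_double_bonds = comp$double_bonds,
      n_acyl_chains = NA_integer_,
      is_lyso = FALSE
    ))
  }
  if (length(chains) != slot) {
    stop(
      sprintf("%s expects %d chain slots, got %d in %s",
              cls, slot, length(chains), dQuote(text, FALSE)),
      call. = FALSE
    )
  }
  chain_df <- data.frame(
    carbons = vapply(chains, `[[`, integer(1), "carbons"),
    double_bonds = vapply(chains, `[[`, integer(1), "double_bonds"),
    sphingoid = vapply(chains, `[[`, logical(1), "sphingoid")
  )
  if (any(chain_df$sphingoid) && !cls %in% c("Cer", "HexCer")) {
    stop(
      sprintf("sphingoid 'd' marker on non-sphingolipid class in %s",
              dQuote(text, FALSE)),
      call. = FALSE
    )
  }
  n_acyl <- sum(chain_df$carbons > 0L)
  .new_lipid_species(
    raw_name = text, lipid_class = cls,
    chains = chain_df,
    resolution = "full_chain",
    isomer_label = isomer,
    total_carbons = sum(chain_df$carbons),
    total_double_bonds = sum(chain_df$double_bonds),
    n_acyl_chains = n_acyl,
    is_lyso = n_acyl < .CANONICAL_ACYL[[cls]]
  )
}

.new_lipid_species <- function(raw_name, lipid_class, chains, resolution,
                               isomer_label, total_carbons, total_double_bonds,
                               n_acyl_chains, is_lyso,
                               alternates = list()) {
  structure(
    list(
      raw_name = raw_name,
      lipid_class = lipid_class,
      chains = chains,
      resolution = resolution,
      isomer_label = isomer_label,
      alternates = alternates,
      total_carbons = total_carbons,
      total_double_bonds = total_double_bonds,
      n_acyl_chains = n_acyl_chains,
      is_lyso = is_lyso,
      charge_class = classify_headgroup_charge(lipid_class, is_lyso)
    ),
    class = "lipid_species"
  )
}

#' Parse a shorthand lipid name
#'
#' Parses names such as `"PG(14:1/15:1)"`, `"PG(18:1/0:0)_A"` (lyso, isomer
#' label), `"PG(35:1)"` (sum composition), `"HexCer(d18:2/16:1)_B"`
#' (sphingoid base) or `"PE(16:0/18:1)/PE(16:1/18:0)"` (ambiguous dual
#' annotation) into a structured species record.
#'
#' Chain slots follow class conventions: cardiolipins carry four, di- and
#' triacylglycerols three (a DG's third slot is canonically `0:0`), all other
#' classes two (ceramides: sphingoid base + N-acyl). A `0:0` slot beyond the
#' class's canonical empty slots marks a lyso species. A single `C:D` term
#' for a multi-slot class is a sum composition with unresolved chains. In an
#' ambiguous dual annotation the first listed species is primary; the others
#' are retained in `$alternates`.
#'
#' @param name A single shorthand lipid name (whitespace is ignored).
#' @return An object of class `lipid_species`: a list with fields
#'   `raw_name`, `lipid_class`, `chains` (data frame with `carbons`,
#'   `double_bonds`, `sphingoid`), `resolution` (`"full_chain"`,
#'   `"sum_composition"` or `"ambiguous"`), `isomer_label`, `alternates`,
#'   `total_carbons`, `total_double_bonds`, `n_acyl_chains`, `is_lyso`,
#'   `charge_class`.
#' @seealso [classify_headgroup_charge()], [chain_summary()],
#'   [format_lipid_name()]
#' @export
#' @examples
#' sp <- parse_lipid_name("PG(14:1/15:1)")
#' sp$total_carbons # 29
#' parse_lipid_name("PG(18:1/0:0)_A")$is_lyso # TRUE
parse_lipid_name <- function(name) {
  if (!is.character(name) || length(name) != 1L || is.na(name) ||
      !nzchar(trimws(name))) {
    stop("`name` must be a single non-empty character string", call. = FALSE)
  }
  clean <- trimws(name)
  annotations <- .split_top_level(gsub(" ", "", clean, fixed = TRUE))
  parsed <- lapply(annotations, .parse_single_annotation, raw_name = clean)
  if (length(parsed) == 1L) {
    sp <- parsed[[1]]
    sp$raw_name <- clean
    return(sp)
  }
  primary <- parsed[[1]]
  .new_lipid_species(
    raw_name = clean,
    lipid_class = primary$lipid_class,
    chains = primary$chains,
    resolution = "ambiguous",
    isomer_label = primary$isomer_label,
    total_carbons = primary$total_carbons,
    total_double_bonds = primary$total_double_bonds,
    n_acyl_chains = primary$n_acyl_chains,
    is_lyso = primary$is_lyso,
    alternates = parsed[-1]
  )
}

#' Render a parsed species back to shorthand text
#'
#' For `full_chain` and `sum_composition` species the output reproduces the
#' canonical input (whitespace stripped); ambiguous species are rendered as
#' the primary annotation joined to its alternates by `/`.
#'
#' @param species A `lipid_species` object.
#' @return A single character string.
#' @export
format_lipid_name <- function(species) {
  stopifnot(inherits(species, "lipid_species"))
  render_one <- function(sp) {
    comp <- if (sp$resolution == "sum_composition") {
      sprintf("%d:%d", sp$total_carbons, sp$total_double_bonds)
    } else {
      paste(
        sprintf("%s%d:%d", ifelse(sp$chains$sphingoid, "d", ""),
                sp$chains$carbons, sp$chains$double_bonds),
        collapse = "/"
      )
    }
    out <- sprintf("%s(%s)", sp$lipid_class, comp)
    if (!is.null(sp$isomer_label)) out <- paste0(out, "_", sp$isomer_label)
    out
  }
  if (species$resolution == "ambiguous") {
    paste(
      c(render_one(species), vapply(species$alternates, render_one, character(1))),
      collapse = "/"
    )
  } else {
    render_one(species)
  }
}

#' @export
print.lipid_species <- function(x, ...) {
  cat(sprintf(
    "<lipid_species> %s\n  class %s (%s), %s%s, C%d:%d, %s\n",
    x$raw_name, x$lipid_class, x$charge_class, x$resolution,
    if (x$is_lyso) ", lyso" else "",
    x$total_carbons, x$total_double_bonds,
    if (is.na(x$n_acyl_chains)) "chains unresolved"
    else sprintf("%d acyl chain(s)", x$n_acyl_chains)
  ))
  invisible(x)
}

#' Classify headgroup net charge
#'
#' Maps a lipid class to its headgroup net-charge class at physiological pH:
#' phosphatidylglycerols, cardiolipins and phosphatidic acids are anionic;
#' phosphatidylcholines and -ethanolamines zwitterionic; glycerolipids (DG,
#' TG) and sphingolipids (Cer, HexCer) neutral. Lyso variants inherit the
#' parent class's assignment.
#'
#' @param lipid_class Character vector of class tokens.
#' @param is_lyso Logical (ignored for the assignment; present so species
#'   records can pass their lyso flag through explicitly).
#' @return Character vector: `"anionic"`, `"zwitterionic"` or `"neutral"`.
#' @export
#' @examples
#' classify_headgroup_charge("PG") # "anionic"
#' classify_headgroup_charge(c("PC", "HexCer"))
classify_headgroup_charge <- function(lipid_class, is_lyso = FALSE) {
  unknown <- setdiff(unique(lipid_class), names(.CHARGE_MAP))
  if (length(unknown) > 0L) {
    stop(
      sprintf("unrecognized lipid class: %s",
              paste(unknown, collapse = ", ")),
      call. = FALSE
    )
  }
  unname(.CHARGE_MAP[lipid_class])
}

#' Summarize the chain composition of a species
#'
#' Returns the quantities consumed by the membrane statistics: total acyl
#' carbons, total double bonds, number of non-empty chains, and the
#' per-lipid chain length used as the weight target in mean-chain-length
#' calculations. By default the chain length of a lipid is its *total*
#' carbon count — the only definition valid for sum-composition species;
#' `basis = "per_chain_mean"` divides by the number of acyl chains instead.
#'
#' @param species A `lipid_species` object.
#' @param basis `"total"` (default) or `"per_chain_mean"`.
#' @return A list with `total_carbons`, `total_double_bonds`,
#'   `n_acyl_chains` and `chain_length`.
#' @export
#' @examples
#' chain_summary(parse_lipid_name("PG(14:1/15:1)"))$chain_length # 29
chain_summary <- function(species, basis = c("total", "per_chain_mean")) {
  stopifnot(inherits(species, "lipid_species"))
  basis <- match.arg(basis)
  len <- if (basis == "total") {
    species$total_carbons
  } else if (is.na(species$n_acyl_chains) || species$n_acyl_chains == 0L) {
    species$total_carbons
  } else {
    species$total_carbons / species$n_acyl_chains
  }
  list(
    total_carbons = species$total_carbons,
    total_double_bonds = species$total_double_bonds,
    n_acyl_chains = species$n_acyl_chains,
    chain_length = len
  )
}

#' Annotate a vector of shorthand names
#'
#' Vectorized wrapper around [parse_lipid_name()] producing one row per
#' name. Names that fail to parse are kept with `NA` annotations and class
#' `"unclassified"` semantics, and a single warning lists them; downstream
#' class-based operations skip such rows.
#'
#' @param names Character vector of shorthand lipid names (must be unique).
#' @param error_on_failure If `TRUE`, a parse failure is an error rather
#'   than a warning.
#' @return A tibble with columns `lipid_id`, `lipid_class`, `charge_class`,
#'   `total_carbons`, `total_double_bonds`, `n_acyl_chains`, `is_lyso`,
#'   `resolution`, `isomer_label`, `parse_ok` and a list-column `species`.
#' @export
annotate_lipids <- function(names, error_on_failure = FALSE) {
  stopifnot(is.character(names), !anyNA(names))
  if (anyDuplicated(names)) {
    stop(
      sprintf("duplicate lipid names: %s",
              paste(unique(names[duplicated(names)]), collapse = ", ")),
      call. = FALSE
    )
  }
  species <- lapply(names, function(nm) {
    tryCatch(parse_lipid_name(nm), error = function(e) e)
  })
  failed <- vapply(species, inherits, logical(1), "error")
  if (any(failed)) {
    msg <- sprintf(
      "%d lipid name(s) failed to parse and are marked unclassified: %s",
      sum(failed), paste(names[failed], collapse = ", ")
    )
    if (error_on_failure) stop(msg, call. = FALSE) else warning(msg, call. = FALSE)
  }
  field <- function(f, default) {
    vapply(species, function(sp) {
      if (inherits(sp, "error")) default else {
        v <- sp[[f]]
        if (is.null(v)) default else v
      }
    }, default)
  }
  tibble(
    lipid_id = names,
    lipid_class = field("lipid_class", NA_character_),
    charge_class = field("charge_class", NA_character_),
    total_carbons = field("total_carbons", NA_integer_),
    total_double_bonds = field("total_double_bonds", NA_integer_),
    n_acyl_chains = field("n_acyl_chains", NA_integer_),
    is_lyso = field("is_lyso", NA),
    resolution = field("resolution", NA_character_),
    isomer_label = field("isomer_label", NA_character_),
    parse_ok = !failed,
    species = lapply(species, function(sp) if (inherits(sp, "error")) NULL else sp)
  )
}
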