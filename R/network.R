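#' Read a genome-scale metabolic network from SBML
#'
#' Parses SBML Level 2 or Level 3 and returns the metabolite and reaction
#' structure needed for matching and subnetwork extraction. ChEBI
#' identifiers are harvested per species from MIRIAM RDF annotations
#' (identifiers.org / obo URI dialects, `CHEBI:<n>` and URL-encoded
#' `CHEBI%3A<n>` alike) and, when a species carries none, from `ChEBI`
#' tokens in its notes body. When several ChEBI ids annotate one species
#' all are kept; the first is used for matching.
#'
#' Compartment duplicates follow the BiGG/Recon id convention: `base_id` is
#' the species id with a trailing `_<compartment>` token removed when that
#' token equals the species' declared compartment, else the id itself.
#'
#' @param path path to an SBML file.
#' @return an object of class `metabolic_network`: list with
#'   `metabolites` (data.frame: `species_id`, `base_id`, `name`,
#'   `compartment`, `chebi_id`, `n_chebi`), `chebi_all` (named list of all
#'   ids per species), `reactions` (named list with `name`, `reversible`,
#'   `substrates`, `products`, `pathway`), and `provenance`.
#' @export
read_sbml <- function(path) {
  if (!file.exists(path)) stop("cannot read SBML file: ", path)
  doc <- tryCatch(xml2::read_xml(path),
                  error = function(e) stop("SBML parse failure: ", conditionMessage(e)))
  level <- xml2::xml_attr(doc, "level")
  version <- xml2::xml_attr(doc, "version")
  xml2::xml_ns_strip(doc)

  sp_nodes <- xml2::xml_find_all(doc, ".//listOfSpecies/species")
  species_id <- xml2::xml_attr(sp_nodes, "id")
  if (anyDuplicated(species_id)) {
    stop("duplicate species id(s): ",
         paste(unique(species_id[duplicated(species_id)]), collapse = ", "))
  }
  name <- xml2::xml_attr(sp_nodes, "name")
  name[is.na(name)] <- species_id[is.na(name)]
  compartment <- xml2::xml_attr(sp_nodes, "compartment")

  chebi_all <- lapply(sp_nodes, .species_chebi)
  names(chebi_all) <- species_id
  chebi_id <- vapply(chebi_all, function(x) if (length(x)) x[1] else NA_character_,
                     character(1))
  multi <- vapply(chebi_all, length, integer(1)) > 1
  if (any(multi)) {
    message(sum(multi), " species carry multiple ChEBI annotations; first kept for matching")
  }

  base_id <- species_id
  has_suffix <- !is.na(compartment) &
    endsWith(species_id, paste0("_", ifelse(is.na(compartment), "", compartment)))
  base_id[has_suffix] <- substr(species_id[has_suffix], 1,
                                nchar(species_id[has_suffix]) -
                                  nchar(compartment[has_suffix]) - 1L)

  metabolites <- data.frame(
    species_id = species_id, base_id = base_id, name = name,
    compartment = compartment, chebi_id = unname(chebi_id),
    n_chebi = vapply(chebi_all, length, integer(1)),
    stringsAsFactors = FALSE)

  rx_nodes <- xml2::xml_find_all(doc, ".//listOfReactions/reaction")
  reactions <- lapply(rx_nodes, .parse_reaction)
  names(reactions) <- vapply(reactions, `[[`, character(1), "reaction_id")
  referenced <- unique(unlist(lapply(reactions, function(r)
    c(r$substrates$species_id, r$products$species_id)), use.names = FALSE))
  dangling <- setdiff(referenced, species_id)
  if (length(dangling) > 0) {
    stop("reaction(s) reference unknown species: ",
         paste(utils::head(dangling, 5), collapse = ", "))
  }

  structure(list(metabolites = metabolites, chebi_all = chebi_all,
                 reactions = reactions,
                 provenance = list(path = path, level = level, version = version)),
            class = "metabolic_network")
}

.CHEBI_URI_RE <- "CHEBI(:|%3A|_)[0-9]+"

.species_chebi <- function(sp) {
  ann <- xml2::xml_find_first(sp, "./annotation")
  ids <- character()
  if (!inherits(ann, "xml_missing")) {
    txt <- as.character(ann)
    hits <- regmatches(txt, gregexpr(.CHEBI_URI_RE, txt, ignore.case = TRUE))[[1]]
    ids <- unique(canonical_chebi(gsub("%3A|_", ":", hits, ignore.case = TRUE)))
  }
  if (length(ids) == 0) {
    notes <- xml2::xml_find_first(sp, "./notes")
    if (!inherits(notes, "xml_missing")) {
      txt <- xml2::xml_text(notes)
      hits <- regmatches(txt, gregexpr("ChEBI[: ]+(CHEBI:)?[0-9]+", txt,
                                       ignore.case = TRUE))[[1]]
      ids <- unique(canonical_chebi(sub("(?i)^ChEBI[: ]+", "", hits, perl = TRUE)))
    }
  }
  ids[!is.na(ids)]
}

.parse_reaction <- function(rx) {
  id <- xml2::xml_attr(rx, "id")
  nm <- xml2::xml_attr(rx, "name")
  rev <- xml2::xml_attr(rx, "reversible")
  rev <- if (is.na(rev)) TRUE else tolower(rev) == "true" # SBML L2 default
  side <- function(xpath) {
    refs <- xml2::xml_find_all(rx, xpath)
    st <- as.numeric(xml2::xml_attr(refs, "stoichiometry"))
    st[is.na(st)] <- 1
    data.frame(species_id = xml2::xml_attr(refs, "species"),
               stoichiometry = st, stringsAsFactors = FALSE)
  }
  notes <- xml2::xml_find_first(rx, "./notes")
  pathway <- NA_character_
  if (!inherits(notes, "xml_missing")) {
    m <- regmatches(xml2::xml_text(notes),
                    regexpr("SUBSYSTEM:\\s*[^<\n]+", xml2::xml_text(notes)))
    if (length(m)) pathway <- trimws(sub("SUBSYSTEM:\\s*", "", m))
  }
  list(reaction_id = id, name = if (is.na(nm)) id else nm, reversible = rev,
       substrates = side("./listOfReactants/speciesReference"),
       products = side("./listOfProducts/speciesReference"),
       pathway = pathway)
}

#' @export
print.metabolic_network <- function(x, ...) {
  cen <- network_census(x)
  cat(sprintf("Metabolic network (%s): %d species, %d reactions\n",
              basename(x$provenance$path %||% "in-memory"),
              cen$species, length(x$reactions)))
  cat(sprintf("  unique compounds: %d; with ChEBI: %d (%.1f%%)\n",
              cen$unique_compounds, cen$chebi_annotated_unique, cen$pct_chebi))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Group compartmentalized species into unique compounds
#'
#' Species sharing a `base_id` are compartment duplicates of one chemical
#' compound. Each group carries a consensus ChEBI id (first seen; a
#' conflict inside a group raises a warning) and a representative name.
#'
#' @param network a `metabolic_network`.
#' @return data.frame with one row per unique compound: `base_id`, `name`,
#'   `chebi_id`, `n_species`, plus attribute `"members"` (named list of
#'   species ids per group).
#' @export
unique_compounds <- function(network) {
  met <- network$metabolites
  if (nrow(met) == 0) {
    out <- data.frame(base_id = character(), name = character(),
                      chebi_id = character(), n_species = integer(),
                      stringsAsFactors = FALSE)
    attr(out, "members") <- list()
    return(out)
  }
  groups <- split(seq_len(nrow(met)), met$base_id)
  rows <- lapply(groups, function(ix) {
    ch <- met$chebi_id[ix]
    ch <- ch[!is.na(ch)]
    if (length(unique(ch)) > 1) {
      warning("conflicting ChEBI ids within compound ", met$base_id[ix[1]],
              "; keeping first seen (", ch[1], ")")
    }
    data.frame(base_id = met$base_id[ix[1]], name = met$name[ix[1]],
               chebi_id = if (length(ch)) ch[1] else NA_character_,
               n_species = length(ix), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  attr(out, "members") <- lapply(groups, function(ix) met$species_id[ix])
  out
}

#' Network census
#'
#' Totals used to assess ChEBI annotation coverage of a network: species
#' count, unique-compound count after compartment de-duplication, number of
#' unique compounds carrying a ChEBI id, and that number as a percentage.
#'
#' @param network a `metabolic_network`.
#' @return list with `species`, `unique_compounds`,
#'   `chebi_annotated_unique`, `pct_chebi` (one decimal).
#' @export
network_census <- function(network) {
  uc <- unique_compounds(network)
  n_sp <- nrow(network$metabolites)
  n_uc <- nrow(uc)
  n_ch <- sum(!is.na(uc$chebi_id))
  list(species = n_sp, unique_compounds = n_uc, chebi_annotated_unique = n_ch,
       pct_chebi = if (n_uc > 0) round(100 * n_ch / n_uc, 1) else 0)
}

.xml_escape <- function(x) {
  x <- gsub("&", "&amp;", x, fixed = TRUE)
  x <- gsub("<", "&lt;", x, fixed = TRUE)
  gsub(">", "&gt;", x, fixed = TRUE)
}

#' Write a metabolic network (or subset) as SBML
#'
#' Emits SBML Level 3 Version 1 with MIRIAM RDF ChEBI annotations on
#' species, sufficient for round-tripping through [read_sbml()]. Used by
#' the fixture generators and by subnetwork export.
#'
#' @param network a `metabolic_network`.
#' @param path output file path.
#' @param species_ids,reaction_ids optional subsets to write (defaults to
#'   the whole network).
#' @return `path`, invisibly.
#' @export
write_sbml <- function(network, path, species_ids = NULL, reaction_ids = NULL) {
  met <- network$metabolites
  if (!is.null(species_ids)) met <- met[met$species_id %in% species_ids, , drop = FALSE]
  rxns <- network$reactions
  if (!is.null(reaction_ids)) rxns <- rxns[names(rxns) %in% reaction_ids]

  comps <- unique(met$compartment)
  comps <- comps[!is.na(comps)]
  lines <- c(
    '<?xml version="1.0" encoding="UTF-8"?>',
    '<sbml xmlns="http://www.sbml.org/sbml/level3/version1/core" level="3" version="1">',
    '  <model id="model">',
    "    <listOfCompartments>",
    sprintf('      <compartment id="%s" constant="true"/>', comps),
    "    </listOfCompartments>",
    "    <listOfSpecies>")
  for (i in seq_len(nrow(met))) {
    sp <- met[i, ]
    open <- sprintf('      <species id="%s" name="%s" compartment="%s" hasOnlySubstanceUnits="false" boundaryCondition="false" constant="false"',
                    sp$species_id, .xml_escape(sp$name), sp$compartment)
    all_ids <- network$chebi_all[[sp$species_id]]
    if (length(all_ids) == 0 && !is.na(sp$chebi_id)) all_ids <- sp$chebi_id
    if (length(all_ids) > 0) {
      lines <- c(lines, paste0(open, ">"),
        "        <annotation><rdf:RDF xmlns:rdf=\"http://www.w3.org/1999/02/22-rdf-syntax-ns#\" xmlns:bqbiol=\"http://biomodels.net/biology-qualifiers/\">",
        sprintf('          <rdf:Description rdf:about="#%s"><bqbiol:is><rdf:Bag>', sp$species_id),
        sprintf('            <rdf:li rdf:resource="http://identifiers.org/chebi/%s"/>', all_ids),
        "          </rdf:Bag></bqbiol:is></rdf:Description>",
        "        </rdf:RDF></annotation>",
        "      </species>")
    } else {
      lines <- c(lines, paste0(open, "/>"))
    }
  }
  lines <- c(lines, "    </listOfSpecies>", "    <listOfReactions>")
  for (r in rxns) {
    side <- function(df, tag) {
      if (nrow(df) == 0) return(character())
      c(sprintf("        <listOf%s>", tag),
        sprintf('          <speciesReference species="%s" stoichiometry="%g" constant="true"/>',
                df$species_id, df$stoichiometry),
        sprintf("        </listOf%s>", tag))
    }
    lines <- c(lines,
      sprintf('      <reaction id="%s" name="%s" reversible="%s" fast="false">',
              r$reaction_id, .xml_escape(r$name), tolower(as.character(r$reversible))),
      side(r$substrates, "Reactants"), side(r$products, "Products"),
      "      </reaction>")
  }
  lines <- c(lines, "    </listOfReactions>", "  </model>", "</sbml>")
  writeLines(lines, path)
  invisible(path)
}
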