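#' SBML export
#'
#' Serializes a model as an SBML Level 3 Version 2 document: one compartment,
#' species with the standard `boundaryCondition` attribute for boundary
#' inputs, global parameters (ids sanitized for SBML, original names kept in
#' the `name` attribute), and kinetic laws written as MathML in the package's
#' rate-law grammar (mass action; Hill with linear catalysts and saturating
#' inhibitors). A compact annotation per reaction records the rate-law
#' structure so the document round-trips exactly; output is deterministic and
#' diff-stable across writes.
#'
#' @param model A `cd4_model`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_sbml <- function(model, path) {
  esc <- function(x) {
    x <- gsub("&", "&amp;", x, fixed = TRUE)
    x <- gsub("<", "&lt;", x, fixed = TRUE)
    gsub(">", "&gt;", x, fixed = TRUE)
  }
  sid <- function(x) gsub(".", "__", x, fixed = TRUE)
  num <- function(x) sprintf("%.17g", x)
  L <- character()
  add <- function(...) L <<- c(L, paste0(...))

  add('<?xml version="1.0" encoding="UTF-8"?>')
  add('<sbml xmlns="http://www.sbml.org/sbml/level3/version2/core" level="3" version="2">')
  md <- model$metadata
  neut <- md$neutralizers
  add('  <model id="', sid(md$model_id %||% "cd4_model"), '" name="CD4 T cell differentiation model">')
  add('    <annotation><cd4:info xmlns:cd4="urn:cd4sim"',
      ' calibration="', esc(md$calibration %||% ""), '"',
      ' model_id="', esc(md$model_id %||% ""), '"',
      ' neutralizers="',
      if (length(neut)) paste0(names(neut), "=", neut, collapse = ";") else "",
      '"/></annotation>')
  add('    <listOfCompartments>')
  add('      <compartment id="cell" spatialDimensions="3" size="1" constant="true"/>')
  add('    </listOfCompartments>')

  add('    <listOfSpecies>')
  for (i in seq_len(nrow(model$species))) {
    s <- model$species[i, ]
    add('      <species id="', s$id, '" name="', esc(s$name),
        '" compartment="cell" initialConcentration="', num(s$initial_level),
        '" hasOnlySubstanceUnits="false" boundaryCondition="',
        tolower(as.character(s$is_boundary)), '" constant="false">')
    add('        <annotation><cd4:species xmlns:cd4="urn:cd4sim" role="',
        s$role, '"/></annotation>')
    add('      </species>')
  }
  add('    </listOfSpecies>')

  add('    <listOfParameters>')
  for (p in names(model$parameters)) {
    add('      <parameter id="', sid(p), '" name="', esc(p), '" value="',
        num(model$parameters[[p]]), '" constant="true"/>')
  }
  add('    </listOfParameters>')

  math_ma <- function(rl, rxn) {
    facs <- c(paste0("<ci> ", sid(rl$k), " </ci>"),
              vapply(names(rxn$substrates), function(s) {
                st <- rxn$substrates[[s]]
                if (st == 1) paste0("<ci> ", s, " </ci>")
                else paste0("<apply><power/><ci> ", s, " </ci><cn> ",
                            num(st), " </cn></apply>")
              }, ""))
    if (length(facs) == 1L) facs else {
      paste0("<apply><times/>", paste0(facs, collapse = ""), "</apply>")
    }
  }
  math_hill <- function(rl) {
    pw <- function(b, e) paste0("<apply><power/><ci> ", b, " </ci><ci> ",
                                e, " </ci></apply>")
    occ <- paste0("<apply><divide/>", pw(rl$driver, sid(rl$n)),
                  "<apply><plus/>", pw(sid(rl$km), sid(rl$n)),
                  pw(rl$driver, sid(rl$n)), "</apply></apply>")
    inh <- vapply(names(rl$inhibitors), function(s) {
      ki <- sid(rl$inhibitors[[s]])
      paste0("<apply><divide/><ci> ", ki, " </ci><apply><plus/><ci> ", ki,
             " </ci><ci> ", s, " </ci></apply></apply>")
    }, "")
    cats <- vapply(rl$catalysts, function(s) paste0("<ci> ", s, " </ci>"), "")
    paste0("<apply><times/><ci> ", sid(rl$vmax), " </ci>",
           paste0(cats, collapse = ""), occ, paste0(inh, collapse = ""),
           "</apply>")
  }

  add('    <listOfReactions>')
  for (rxn in model$reactions) {
    rl <- rxn$rate_law
    add('      <reaction id="', rxn$id, '" reversible="false">')
    ann <- if (rl$kind == "mass_action") {
      paste0('kind="mass_action" k="', sid(rl$k), '"')
    } else {
      inh_txt <- if (length(rl$inhibitors)) {
        paste0(names(rl$inhibitors), "=", sid(unname(rl$inhibitors)),
               collapse = " ")
      } else ""
      paste0('kind="hill" vmax="', sid(rl$vmax), '" km="', sid(rl$km),
             '" n="', sid(rl$n), '" driver="', rl$driver,
             '" catalysts="', paste(rl$catalysts, collapse = " "),
             '" inhibitors="', inh_txt, '"')
    }
    add('        <annotation><cd4:rateLaw xmlns:cd4="urn:cd4sim" ', ann,
        '/></annotation>')
    if (length(rxn$substrates)) {
      add('        <listOfReactants>')
      for (s in names(rxn$substrates)) {
        add('          <speciesReference species="', s, '" stoichiometry="',
            num(rxn$substrates[[s]]), '" constant="true"/>')
      }
      add('        </listOfReactants>')
    }
    if (length(rxn$products)) {
      add('        <listOfProducts>')
      for (s in names(rxn$products)) {
        add('          <speciesReference species="', s, '" stoichiometry="',
            num(rxn$products[[s]]), '" constant="true"/>')
      }
      add('        </listOfProducts>')
    }
    if (length(rxn$modifiers)) {
      add('        <listOfModifiers>')
      for (s in rxn$modifiers) {
        add('          <modifierSpeciesReference species="', s, '"/>')
      }
      add('        </listOfModifiers>')
    }
    add('        <kineticLaw>')
    add('          <math xmlns="http://www.w3.org/1998/Math/MathML">')
    add('            ', if (rl$kind == "mass_action") math_ma(rl, rxn) else math_hill(rl))
    add('          </math>')
    add('        </kineticLaw>')
    add('      </reaction>')
  }
  add('    </listOfReactions>')
  add('  </model>')
  add('</sbml>')
  writeLines(L, path)
  invisible(path)
}

#' SBML import
#'
#' Reads an SBML Level 2 or Level 3 document into a `cd4_model`. Kinetic
#' laws are reconstructed from the package's rate-law annotation when
#' present; otherwise plain mass-action MathML (a product of one rate
#' constant and species factors with optional integer powers) is parsed.
#' Unsupported constructs -- events, algebraic/assignment/rate rules,
#' constraints, function definitions, unrecognized kinetic laws -- are
#' rejected with a clear message.
#'
#' @param path Path to an SBML file.
#' @return A `cd4_model`.
#' @export
read_sbml <- function(path) {
  doc <- xml2::read_xml(path)
  if (xml2::xml_name(doc) != "sbml") stop("not an SBML document")
  level <- xml2::xml_attr(doc, "level")
  if (!level %in% c("2", "3")) {
    stop("unsupported SBML level: ", level %||% "missing")
  }
  findall <- function(node, what) {
    xml2::xml_find_all(node, paste0(".//*[local-name()='", what, "']"))
  }
  for (bad in c("event", "algebraicRule", "assignmentRule", "rateRule",
                "constraint", "functionDefinition", "initialAssignment")) {
    if (length(findall(doc, bad))) {
      stop("unsupported SBML construct: ", bad)
    }
  }

  sp_nodes <- xml2::xml_find_all(
    doc, ".//*[local-name()='listOfSpecies']/*[local-name()='species']")
  if (!length(sp_nodes)) stop("SBML document contains no species")
  species <- do.call(rbind, lapply(sp_nodes, function(nd) {
    init <- xml2::xml_attr(nd, "initialConcentration")
    if (is.na(init)) init <- xml2::xml_attr(nd, "initialAmount")
    role_nd <- xml2::xml_find_first(nd, ".//*[local-name()='species' and @role]")
    role <- if (!inherits(role_nd, "xml_missing")) {
      xml2::xml_attr(role_nd, "role")
    } else NA
    cd4_species(
      id = xml2::xml_attr(nd, "id"),
      name = xml2::xml_attr(nd, "name") %|NA|% xml2::xml_attr(nd, "id"),
      role = role %|NA|% "signal_transducer",
      initial_level = as.numeric(init %|NA|% 0),
      is_boundary = identical(xml2::xml_attr(nd, "boundaryCondition"), "true")
    )
  }))

  par_nodes <- xml2::xml_find_all(
    doc, ".//*[local-name()='listOfParameters']/*[local-name()='parameter']")
  par_ids <- xml2::xml_attr(par_nodes, "id")
  par_names <- xml2::xml_attr(par_nodes, "name")
  orig <- ifelse(is.na(par_names) | par_names == "",
                 gsub("__", ".", par_ids, fixed = TRUE), par_names)
  parameters <- stats::setNames(as.numeric(xml2::xml_attr(par_nodes, "value")),
                                orig)
  unsid <- stats::setNames(orig, par_ids)
  to_param <- function(id) {
    if (id %in% names(unsid)) unsid[[id]] else
      stop("kinetic law references unknown parameter: ", id)
  }

  parse_ma_math <- function(math, id) {
    apply_nd <- xml2::xml_find_first(math, ".//*[local-name()='apply']")
    cis <- if (inherits(apply_nd, "xml_missing")) {
      findall(math, "ci")
    } else {
      kids <- xml2::xml_children(apply_nd)
      if (!length(kids) || xml2::xml_name(kids[[1]]) != "times") {
        stop("unsupported kinetic law in reaction ", id,
             " (expected a mass-action product or a rate-law annotation)")
      }
      kids[-1]
    }
    k <- NULL
    for (nd in cis) {
      nm <- xml2::xml_name(nd)
      tok <- if (nm == "ci") trimws(xml2::xml_text(nd)) else {
        # <apply><power/><ci>base</ci><cn>exp</cn></apply>
        trimws(xml2::xml_text(xml2::xml_child(nd, 2)))
      }
      if (is.null(k) && tok %in% names(unsid)) k <- to_param(tok)
      else if (tok %in% species$id) NULL
      else if (tok %in% names(unsid)) {
        stop("unsupported kinetic law in reaction ", id,
             ": multiple parameter factors")
      } else stop("kinetic law references unknown identifier: ", tok)
    }
    if (is.null(k)) stop("no rate constant found in kinetic law of ", id)
    ma_law(k)
  }

  rx_nodes <- findall(doc, "reaction")
  reactions <- lapply(rx_nodes, function(nd) {
    id <- xml2::xml_attr(nd, "id")
    get_refs <- function(list_name) {
      refs <- xml2::xml_find_all(nd, paste0(
        ".//*[local-name()='", list_name, "']/*"))
      if (!length(refs)) return(numeric())
      sto <- as.numeric(xml2::xml_attr(refs, "stoichiometry"))
      sto[is.na(sto)] <- 1
      stats::setNames(sto, xml2::xml_attr(refs, "species"))
    }
    substrates <- get_refs("listOfReactants")
    products <- get_refs("listOfProducts")
    mods <- xml2::xml_attr(
      xml2::xml_find_all(nd, ".//*[local-name()='listOfModifiers']/*"),
      "species")
    ann <- xml2::xml_find_first(nd, ".//*[local-name()='rateLaw']")
    rl <- if (!inherits(ann, "xml_missing")) {
      kind <- xml2::xml_attr(ann, "kind")
      if (kind == "mass_action") {
        ma_law(to_param(xml2::xml_attr(ann, "k")))
      } else {
        inh_txt <- xml2::xml_attr(ann, "inhibitors")
        inh <- character()
        if (!is.na(inh_txt) && nzchar(inh_txt)) {
          parts <- strsplit(strsplit(inh_txt, " ", fixed = TRUE)[[1]], "=",
                            fixed = TRUE)
          inh <- stats::setNames(
            vapply(parts, function(p) to_param(p[2]), ""),
            vapply(parts, `[[`, "", 1))
        }
        cat_txt <- xml2::xml_attr(ann, "catalysts")
        cats <- if (!is.na(cat_txt) && nzchar(cat_txt)) {
          strsplit(cat_txt, " ", fixed = TRUE)[[1]]
        } else character()
        hill_law(vmax = to_param(xml2::xml_attr(ann, "vmax")),
                 km = to_param(xml2::xml_attr(ann, "km")),
                 n = to_param(xml2::xml_attr(ann, "n")),
                 driver = xml2::xml_attr(ann, "driver"),
                 inhibitors = inh, catalysts = cats)
      }
    } else {
      math <- xml2::xml_find_first(nd, ".//*[local-name()='math']")
      if (inherits(math, "xml_missing")) {
        stop("reaction ", id, " has no kinetic law")
      }
      parse_ma_math(math, id)
    }
    cd4_reaction(id, substrates = substrates, products = products,
                 rate_law = rl, modifiers = mods)
  })

  info <- xml2::xml_find_first(doc, ".//*[local-name()='info']")
  metadata <- list()
  if (!inherits(info, "xml_missing")) {
    metadata$calibration <- xml2::xml_attr(info, "calibration") %|NA|% NULL
    metadata$model_id <- xml2::xml_attr(info, "model_id") %|NA|% NULL
    nt <- xml2::xml_attr(info, "neutralizers")
    if (!is.na(nt) && nzchar(nt)) {
      parts <- strsplit(strsplit(nt, ";", fixed = TRUE)[[1]], "=", fixed = TRUE)
      metadata$neutralizers <- stats::setNames(
        vapply(parts, `[[`, "", 2), vapply(parts, `[[`, "", 1))
    }
  }
  define_model(species, reactions, parameters, metadata = metadata)
}

`%|NA|%` <- function(a, b) if (length(a) == 1 && is.na(a)) b else a
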