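# SBML interchange. Writing emits Level 3 Version 1 with the fbc version 2
# extension (flux bounds as parameters, GPRs as geneProductAssociations, the
# biomass reaction as the active maximisation objective). Reading sniffs the
# document rather than assuming a level: L3+fbc is preferred, and L2 documents
# with note-encoded GENE_ASSOCIATION strings and kineticLaw LOWER_BOUND /
# UPPER_BOUND / OBJECTIVE_COEFFICIENT parameters are tolerated.
#
# SBML SIds cannot carry characters such as '[' or ']'; ids are mangled with
# the conventional "__<ascii code>__" escape plus M_/R_/G_ prefixes, and
# demangled on read, so arbitrary metabolite/reaction ids round-trip.

FBC_NS <- "http://www.sbml.org/sbml/level3/version1/fbc/version2"

mangle_sid <- function(id, prefix) {
  chars <- strsplit(id, "")[[1]]
  ok <- grepl("[A-Za-z0-9_]", chars)
  chars[!ok] <- vapply(chars[!ok], function(ch) {
    sprintf("__%d__", utf8ToInt(ch))
  }, character(1))
  paste0(prefix, paste(chars, collapse = ""))
}

demangle_sid <- function(sid, prefix) {
  id <- sub(paste0("^", prefix), "", sid)
  while (grepl("__([0-9]+)__", id)) {
    m <- regmatches(id, regexpr("__([0-9]+)__", id))
    code <- as.integer(gsub("__", "", m))
    id <- sub(m, intToUtf8(code), id, fixed = TRUE)
  }
  id
}

xml_escape <- function(x) {
  x <- gsub("&", "&amp;", x, fixed = TRUE)
  x <- gsub("<", "&lt;", x, fixed = TRUE)
  x <- gsub(">", "&gt;", x, fixed = TRUE)
  gsub("\"", "&quot;", x, fixed = TRUE)
}

#' Write a model as SBML (Level 3 + fbc v2)
#'
#' @param model A [gsm()].
#' @param path Output file path.
#' @return Invisibly, the path.
#' @export
write_sbml <- function(model, path) {
  if (nrow(model$reactions) == 0) {
    stop("refusing to serialize a model with no reactions", call. = FALSE)
  }
  validate_gsm(model)
  rx <- model$reactions
  mets <- model$metabolites
  genes <- gene_ids(model)

  lines <- c(
    "<?xml version=\"1.0\" encoding=\"UTF-8\"?>",
    paste0("<sbml xmlns=\"http://www.sbml.org/sbml/level3/version1/core\" ",
           "xmlns:fbc=\"", FBC_NS, "\" level=\"3\" version=\"1\" ",
           "fbc:required=\"false\">"),
    "  <model id=\"model\" fbc:strict=\"true\">",
    "    <listOfCompartments>"
  )
  for (cmp in unique(mets$compartment)) {
    lines <- c(lines, sprintf(
      "      <compartment id=\"%s\" constant=\"true\"/>",
      mangle_sid(cmp, "C_")))
  }
  lines <- c(lines, "    </listOfCompartments>", "    <listOfSpecies>")
  for (i in seq_len(nrow(mets))) {
    lines <- c(lines, sprintf(
      paste0("      <species id=\"%s\" name=\"%s\" compartment=\"%s\" ",
             "hasOnlySubstanceUnits=\"false\" boundaryCondition=\"false\" ",
             "constant=\"false\"/>"),
      mangle_sid(mets$id[i], "M_"), xml_escape(mets$name[i]),
      mangle_sid(mets$compartment[i], "C_")))
  }
  lines <- c(lines, "    </listOfSpecies>", "    <listOfParameters>")
  bounds <- sort(unique(c(rx$lower_bound, rx$upper_bound)))
  bound_id <- function(v) sprintf("bnd_%s", gsub("[^0-9A-Za-z]", "_",
                                                 format(v, scientific = FALSE)))
  for (v in bounds) {
    lines <- c(lines, sprintf(
      "      <parameter id=\"%s\" value=\"%s\" constant=\"true\"/>",
      bound_id(v), format(v, scientific = FALSE)))
  }
  lines <- c(lines, "    </listOfParameters>")

  if (length(genes) > 0) {
    lines <- c(lines, "    <fbc:listOfGeneProducts>")
    for (g in genes) {
      lines <- c(lines, sprintf(
        "      <fbc:geneProduct fbc:id=\"%s\" fbc:label=\"%s\"/>",
        mangle_sid(g, "G_"), xml_escape(g)))
    }
    lines <- c(lines, "    </fbc:listOfGeneProducts>")
  }

  gpr_xml <- function(node, indent) {
    pad <- strrep(" ", indent)
    if (is.character(node)) {
      return(sprintf("%s<fbc:geneProductRef fbc:geneProduct=\"%s\"/>",
                     pad, mangle_sid(node, "G_")))
    }
    tag <- if (node$op == "and") "fbc:and" else "fbc:or"
    c(sprintf("%s<%s>", pad, tag),
      unlist(lapply(node$args, gpr_xml, indent = indent + 2)),
      sprintf("%s</%s>", pad, tag))
  }

  lines <- c(lines, "    <listOfReactions>")
  for (i in seq_len(nrow(rx))) {
    s <- rx$stoichiometry[[i]]
    lines <- c(lines, sprintf(
      paste0("      <reaction id=\"%s\" reversible=\"%s\" fast=\"false\" ",
             "fbc:lowerFluxBound=\"%s\" fbc:upperFluxBound=\"%s\">"),
      mangle_sid(rx$id[i], "R_"),
      if (rx$lower_bound[i] < 0) "true" else "false",
      bound_id(rx$lower_bound[i]), bound_id(rx$upper_bound[i])))
    reactants <- s[s < 0]
    products <- s[s > 0]
    if (length(reactants) > 0) {
      lines <- c(lines, "        <listOfReactants>")
      for (j in seq_along(reactants)) {
        lines <- c(lines, sprintf(
          paste0("          <speciesReference species=\"%s\" ",
                 "stoichiometry=\"%s\" constant=\"true\"/>"),
          mangle_sid(names(reactants)[j], "M_"),
          format(abs(reactants[[j]]), scientific = FALSE)))
      }
      lines <- c(lines, "        </listOfReactants>")
    }
    if (length(products) > 0) {
      lines <- c(lines, "        <listOfProducts>")
      for (j in seq_along(products)) {
        lines <- c(lines, sprintf(
          paste0("          <speciesReference species=\"%s\" ",
                 "stoichiometry=\"%s\" constant=\"true\"/>"),
          mangle_sid(names(products)[j], "M_"),
          format(products[[j]], scientific = FALSE)))
      }
      lines <- c(lines, "        </listOfProducts>")
    }
    if (nzchar(rx$gpr[i])) {
      lines <- c(lines,
                 "        <fbc:geneProductAssociation>",
                 gpr_xml(parse_gpr(rx$gpr[i]), 10),
                 "        </fbc:geneProductAssociation>")
    }
    lines <- c(lines, "      </reaction>")
  }
  lines <- c(lines, "    </listOfReactions>")
  lines <- c(lines,
    "    <fbc:listOfObjectives fbc:activeObjective=\"obj\">",
    "      <fbc:objective fbc:id=\"obj\" fbc:type=\"maximize\">",
    "        <fbc:listOfFluxObjectives>",
    sprintf(paste0("          <fbc:fluxObjective fbc:reaction=\"%s\" ",
                   "fbc:coefficient=\"1\"/>"),
            mangle_sid(model$biomass_reaction_id, "R_")),
    "        </fbc:listOfFluxObjectives>",
    "      </fbc:objective>",
    "    </fbc:listOfObjectives>",
    "  </model>",
    "</sbml>")
  writeLines(lines, path)
  # re-parse to guarantee the emitted document is well-formed XML
  invisible(xml2::read_xml(path))
  invisible(path)
}

#' Read a model from SBML
#'
#' Accepts Level 3 with the fbc extension, or Level 2 with note-encoded
#' GENE_ASSOCIATION strings and kineticLaw bound parameters. Reactions
#' without stated bounds default to -10,000/10,000 (0 lower when marked
#' irreversible). The biomass reaction is taken from the active fbc
#' objective (or the L2 OBJECTIVE_COEFFICIENT convention) unless supplied.
#'
#' @param path SBML file path.
#' @param biomass_reaction_id Optional explicit biomass reaction id
#'   (demangled form), overriding the document's objective.
#' @return A [gsm()].
#' @export
read_sbml <- function(path, biomass_reaction_id = NULL) {
  doc <- xml2::read_xml(path) # malformed XML errors here, naming the line
  ns <- xml2::xml_ns(doc)
  core <- names(ns)[startsWith(unname(ns), "http://www.sbml.org/sbml/")][1]
  has_fbc <- any(unname(ns) == FBC_NS)
  fbc <- if (has_fbc) names(ns)[unname(ns) == FBC_NS][1] else NULL
  q <- function(tag) paste0(core, ":", tag)

  species_nodes <- xml2::xml_find_all(doc, paste0(".//", q("listOfSpecies"),
                                                  "/", q("species")))
  mets <- tibble::tibble(
    sid = xml2::xml_attr(species_nodes, "id"),
    name = xml2::xml_attr(species_nodes, "name"),
    compartment = unname(vapply(xml2::xml_attr(species_nodes, "compartment"),
                                demangle_sid, character(1), prefix = "C_"))
  )
  mets$id <- unname(vapply(mets$sid, demangle_sid, character(1),
                           prefix = "M_"))
  mets$name[is.na(mets$name)] <- mets$id[is.na(mets$name)]
  sid_to_id <- stats::setNames(mets$id, mets$sid)

  params <- xml2::xml_find_all(doc, paste0(".//", q("model"), "/",
                                           q("listOfParameters"), "/",
                                           q("parameter")))
  param_values <- stats::setNames(
    as.numeric(xml2::xml_attr(params, "value")),
    xml2::xml_attr(params, "id"))

  gp_nodes <- if (has_fbc) {
    xml2::xml_find_all(doc, paste0(".//", fbc, ":listOfGeneProducts/",
                                   fbc, ":geneProduct"))
  } else {
    list()
  }
  fattr <- function(node, name) {
    v <- xml2::xml_attr(node, paste0(fbc, ":", name), ns = ns)
    if (is.na(v)) xml2::xml_attr(node, name) else v
  }
  gp_label <- stats::setNames(
    vapply(gp_nodes, function(n) {
      lbl <- fattr(n, "label")
      if (is.na(lbl)) demangle_sid(fattr(n, "id"), "G_") else lbl
    }, character(1)),
    vapply(gp_nodes, function(n) fattr(n, "id"), character(1)))

  gpa_to_string <- function(node) {
    name <- xml2::xml_name(node)
    if (name == "geneProductRef") {
      sid <- fattr(node, "geneProduct")
      lbl <- gp_label[sid]
      return(if (is.na(lbl)) demangle_sid(sid, "G_") else unname(lbl))
    }
    children <- xml2::xml_children(node)
    parts <- vapply(children, gpa_to_string, character(1))
    wrapped <- vapply(parts, function(p) {
      if (grepl("\\s", p)) paste0("(", p, ")") else p
    }, character(1))
    paste(wrapped, collapse = paste0(" ", name, " "))
  }

  rx_nodes <- xml2::xml_find_all(doc, paste0(".//", q("listOfReactions"),
                                             "/", q("reaction")))
  objective_id <- NULL
  n_rx <- length(rx_nodes)
  ids <- character(n_rx)
  lbs <- numeric(n_rx)
  ubs <- numeric(n_rx)
  gprs <- character(n_rx)
  subsystems <- character(n_rx)
  stoichs <- vector("list", n_rx)

  for (i in seq_len(n_rx)) {
    node <- rx_nodes[[i]]
    sid <- xml2::xml_attr(node, "id")
    ids[i] <- demangle_sid(sid, "R_")
    reversible <- !identical(xml2::xml_attr(node, "reversible"), "false")

    stoich <- numeric(0)
    for (side in c("listOfReactants", "listOfProducts")) {
      sign <- if (side == "listOfReactants") -1 else 1
      refs <- xml2::xml_find_all(node, paste0("./", q(side), "/",
                                              q("speciesReference")))
      for (ref in refs) {
        ssid <- xml2::xml_attr(ref, "species")
        met <- sid_to_id[ssid]
        if (is.na(met)) {
          stop("reaction '", ids[i], "' references undeclared species '",
               ssid, "'", call. = FALSE)
        }
        coef <- as.numeric(xml2::xml_attr(ref, "stoichiometry"))
        if (is.na(coef)) coef <- 1
        stoich[met] <- (if (met %in% names(stoich)) stoich[[met]] else 0) +
          sign * coef
      }
    }
    stoichs[[i]] <- stoich[stoich != 0]

    lb <- NA_real_
    ub <- NA_real_
    if (has_fbc) {
      lb_ref <- fattr(node, "lowerFluxBound")
      ub_ref <- fattr(node, "upperFluxBound")
      if (!is.na(lb_ref)) lb <- param_values[lb_ref]
      if (!is.na(ub_ref)) ub <- param_values[ub_ref]
    }
    klaw_params <- xml2::xml_find_all(node, paste0("./", q("kineticLaw"),
                                                   "//", q("parameter")))
    if (length(klaw_params) > 0) {
      kp <- stats::setNames(as.numeric(xml2::xml_attr(klaw_params, "value")),
                            xml2::xml_attr(klaw_params, "id"))
      if ("LOWER_BOUND" %in% names(kp)) lb <- kp[["LOWER_BOUND"]]
      if ("UPPER_BOUND" %in% names(kp)) ub <- kp[["UPPER_BOUND"]]
      oc <- kp["OBJECTIVE_COEFFICIENT"]
      if (!is.na(oc) && oc != 0) objective_id <- ids[i]
    }
    if (is.na(lb)) lb <- if (reversible) -DEFAULT_BOUND else 0
    if (is.na(ub)) ub <- DEFAULT_BOUND
    lbs[i] <- lb
    ubs[i] <- ub

    gpr <- ""
    if (has_fbc) {
      gpa <- xml2::xml_find_first(node, paste0("./", fbc,
                                               ":geneProductAssociation"))
      if (!inherits(gpa, "xml_missing")) {
        gpr <- gpa_to_string(xml2::xml_child(gpa))
      }
    }
    if (!nzchar(gpr)) {
      notes <- xml2::xml_find_all(node, paste0("./", q("notes"), "//*"))
      note_text <- xml2::xml_text(notes)
      ga <- note_text[grepl("GENE_ASSOCIATION", note_text)]
      if (length(ga) > 0) {
        gpr <- trimws(sub(".*GENE_ASSOCIATION\\s*:", "", ga[1]))
      }
      ss <- note_text[grepl("SUBSYSTEM", note_text)]
      if (length(ss) > 0) {
        subsystems[i] <- trimws(sub(".*SUBSYSTEM\\s*:", "", ss[1]))
      }
    }
    gprs[i] <- gpr
  }

  if (has_fbc && is.null(objective_id)) {
    act <- xml2::xml_find_first(doc, paste0(".//", fbc, ":listOfObjectives"))
    if (!inherits(act, "xml_missing")) {
      fo <- xml2::xml_find_first(doc, paste0(".//", fbc, ":fluxObjective"))
      if (!inherits(fo, "xml_missing")) {
        objective_id <- demangle_sid(fattr(fo, "reaction"), "R_")
      }
    }
  }
  biomass <- biomass_reaction_id %||% objective_id
  if (is.null(biomass)) {
    stop("no reaction is flagged as the objective and no biomass_reaction_id ",
         "was configured", call. = FALSE)
  }

  gsm(
    tibble::tibble(id = ids, stoichiometry = stoichs, lower_bound = lbs,
                   upper_bound = ubs, gpr = gprs, subsystem = subsystems),
    mets[, c("id", "name", "compartment")],
    biomass_reaction_id = biomass
  )
}
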