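#' Synthetic SBML version pairs with ground-truth mutation logs
#'
#' The generator emulates the condensed SBML structure the pipeline consumes:
#' a random compartment forest, species assigned to compartments (a chosen
#' fraction annotated with SBO terms from the packaged mapping tables), and
#' reactions wiring 1-3 reactants, 1-3 products and 0-2 modifiers, with
#' kinetic laws on about half the reactions. [mutate()] then applies a
#' requested number of mutually consistent random mutations and returns both
#' documents together with the exact mutation log, which serves as ground
#' truth for the diff engine.
#'
#' @name fixtures
NULL

.SPECIES_SBO_POOL <- c("SBO:0000247", "SBO:0000245", "SBO:0000250",
                       "SBO:0000251", "SBO:0000253", "SBO:0000285",
                       "SBO:0000327", "SBO:0000252", "SBO:0000297")
.MODIFIER_SBO_POOL <- c("SBO:0000013", "SBO:0000020", "SBO:0000459",
                        "SBO:0000461", "SBO:0000019", "SBO:0000460",
                        "SBO:0000206")

with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else assign(".Random.seed", old, envir = globalenv())
  }, add = TRUE)
  set.seed(as.integer(seed))
  force(expr)
}

#' Generate a deterministic synthetic SBML document
#'
#' @param n_species,n_reactions,n_compartments entity counts
#'   (`n_species >= 1`, `n_compartments >= 1`, `n_reactions >= 0`)
#' @param sbo_coverage fraction of species and modifier links carrying SBO
#'   terms, in `[0, 1]`
#' @param seed integer; identical arguments and seed give byte-identical
#'   documents
#' @return SBML document text with the generated `sbml_model` attached as
#'   attribute `"model"`
#' @export
generate_base_model <- function(n_species, n_reactions, n_compartments,
                                sbo_coverage = 0.5, seed = 1L) {
  if (n_species < 1 || n_compartments < 1 || n_reactions < 0) {
    stop_sbgndiff("sbgndiff_parameter_error",
                  "need at least one species and compartment, non-negative reactions")
  }
  if (sbo_coverage < 0 || sbo_coverage > 1) {
    stop_sbgndiff("sbgndiff_parameter_error",
                  "sbo_coverage must lie in [0, 1]")
  }
  if (n_reactions > 0 && n_species < 1) {
    stop_sbgndiff("sbgndiff_parameter_error",
                  "reactions need species to wire")
  }
  m <- with_seed(seed, {
    comps <- lapply(seq_len(n_compartments), function(i) {
      id <- sprintf("comp%d", i)
      at <- c(id = id, name = sprintf("compartment %d", i), size = "1")
      if (i > 1L && stats::runif(1) < 0.4) {
        at[["outside"]] <- sprintf("comp%d", sample.int(i - 1L, 1L))
      }
      new_compartment(id, name = at[["name"]],
                      parent = attr_or_na(at, "outside"), attributes = at)
    })
    specs <- lapply(seq_len(n_species), function(i) {
      id <- sprintf("spec%d", i)
      comp <- sprintf("comp%d", sample.int(n_compartments, 1L))
      at <- c(id = id, name = sprintf("species %d", i), compartment = comp,
              metaid = sprintf("meta_%s", id))
      if (stats::runif(1) < sbo_coverage) {
        at[["sboTerm"]] <- sample(.SPECIES_SBO_POOL, 1L)
      }
      if (stats::runif(1) < 0.5) {
        at[["initialConcentration"]] <- sprintf("%.2f", stats::runif(1, 0, 10))
      }
      new_species(id, name = at[["name"]], compartment = comp,
                  sbo_term = attr_or_na(at, "sboTerm"), attributes = at)
    })
    rxns <- lapply(seq_len(n_reactions), function(i) {
      id <- sprintf("rxn%d", i)
      n_re <- sample.int(min(3L, n_species), 1L)
      n_pr <- sample.int(min(3L, n_species), 1L)
      n_mo <- sample.int(3L, 1L) - 1L
      pick <- function(n) sprintf("spec%d", sample.int(n_species, n))
      re <- pick(n_re); pr <- pick(n_pr)
      mo <- setdiff(sprintf("spec%d", sample.int(n_species, min(n_mo + 2L, n_species))),
                    c(re, pr))
      mo <- utils::head(mo, n_mo)
      part <- function(sp, role) {
        at <- c(species = sp)
        if (role != "modifier") at[["stoichiometry"]] <- "1"
        if (role == "modifier" && stats::runif(1) < sbo_coverage) {
          at[["sboTerm"]] <- sample(.MODIFIER_SBO_POOL, 1L)
        }
        new_participant(sp, role, sbo_term = attr_or_na(at, "sboTerm"),
                        stoichiometry = if (role == "modifier") NA_real_ else 1,
                        attributes = at)
      }
      kl <- if (stats::runif(1) < 0.5) {
        k <- sprintf("%.3f", stats::runif(1, 0.01, 2))
        new_kinetic_law(
          math = math_node("math", children = list(
            math_node("apply", children = list(
              math_node("times"),
              math_node("ci", text = "k1"),
              math_node("ci", text = re[1L])
            ))
          )),
          local_parameters = list(k1 = c(id = "k1", value = k))
        )
      } else NULL
      at <- c(id = id, name = sprintf("reaction %d", i), reversible = "false",
              metaid = sprintf("meta_%s", id))
      new_reaction(id, name = at[["name"]], reversible = FALSE,
                   reactants = lapply(re, part, role = "reactant"),
                   products = lapply(pr, part, role = "product"),
                   modifiers = lapply(mo, part, role = "modifier"),
                   kinetic_law = kl, attributes = at)
    })
    new_sbml_model(sprintf("synthetic_model_seed%d", as.integer(seed)),
                   comps, specs, rxns)
  })
  structure(write_sbml(m), model = m)
}

# -- mutation machinery ------------------------------------------------------

mutation_kinds <- c("add_species", "delete_species", "update_attribute",
                    "add_compartment", "delete_compartment",
                    "change_participant_role", "add_reaction",
                    "delete_reaction", "edit_kinetic_law", "move_element")

log_row <- function(kind, entity_kind, subject, param = NA_character_,
                    old = NA_character_, new = NA_character_) {
  data.frame(kind = kind, entity_kind = entity_kind, subject = subject,
             param = param, old = old, new = new, stringsAsFactors = FALSE)
}

# sync convenience fields from an entity's attribute map
resync_species <- function(e) {
  e$name <- attr_or_na(e$attributes, "name")
  e$compartment <- attr_or_na(e$attributes, "compartment")
  e$sbo_term <- attr_or_na(e$attributes, "sboTerm")
  e
}

#' Apply random, mutually consistent mutations to an SBML document
#'
#' Chooses `n_mutations` feasible mutations (each touching a subject no
#' earlier mutation touched, so the log maps one-to-one onto expected change
#' classes), applies them, and returns both versions plus the exact log.
#'
#' @param model SBML document text (version A)
#' @param n_mutations number of mutations to apply
#' @param seed integer RNG seed
#' @return object of class `fixture_pair`: list with `model_a`, `model_b`
#'   (SBML texts), `log` (data.frame), `seed`
#' @export
mutate <- function(model, n_mutations, seed = 1L) {
  if (n_mutations < 0) {
    stop_sbgndiff("sbgndiff_parameter_error", "n_mutations must be >= 0")
  }
  m <- read_sbml(model)
  logs <- list()
  touched <- character()
  with_seed(seed, {
    for (step in seq_len(n_mutations)) {
      applied <- FALSE
      for (kind in sample(mutation_kinds)) {
        res <- try_mutation(kind, m, touched, step)
        if (!is.null(res)) {
          m <- res$model
          touched <- c(touched, res$touched)
          logs[[length(logs) + 1L]] <- res$log
          applied <- TRUE
          break
        }
      }
      if (!applied) {
        stop_sbgndiff("sbgndiff_parameter_error",
                      "no feasible mutation left at step %d", step)
      }
    }
  })
  log <- if (length(logs)) do.call(rbind, logs) else
    log_row("x", "x", "x")[0, ]
  structure(list(model_a = as.character(model), model_b = write_sbml(m),
                 log = log, seed = as.integer(seed)),
            class = "fixture_pair")
}

#' @export
print.fixture_pair <- function(x, ...) {
  cat(sprintf("<fixture_pair: %d mutations, seed %d>\n", nrow(x$log), x$seed))
  invisible(x)
}

untouched <- function(ids, kind, touched) {
  if (!length(ids)) return(character())
  ids[!(paste0(kind, ":", ids) %in% touched)]
}

try_mutation <- function(kind, m, touched, step) {
  sp_ids <- entity_ids(m$species)
  comp_ids <- entity_ids(m$compartments)
  rx_ids <- entity_ids(m$reactions)
  referenced_species <- unique(unlist(lapply(m$reactions, function(r) {
    vapply(c(r$reactants, r$products, r$modifiers), `[[`, "", "species")
  })))
  switch(kind,
    add_species = {
      if (!length(comp_ids)) return(NULL)
      id <- sprintf("added_spec_%d", step)
      comp <- sample(comp_ids, 1L)
      at <- c(id = id, name = sprintf("added species %d", step),
              compartment = comp, metaid = sprintf("meta_%s", id))
      m$species[[length(m$species) + 1L]] <-
        new_species(id, name = at[["name"]], compartment = comp,
                    attributes = at)
      list(model = m, touched = paste0("species:", id),
           log = log_row("add_species", "species", id))
    },
    delete_species = {
      cand <- untouched(setdiff(sp_ids, referenced_species), "species", touched)
      if (!length(cand)) return(NULL)
      id <- sample(cand, 1L)
      m$species[[which(sp_ids == id)]] <- NULL
      list(model = m, touched = paste0("species:", id),
           log = log_row("delete_species", "species", id))
    },
    update_attribute = {
      pools <- list(species = untouched(sp_ids, "species", touched),
                    compartment = untouched(comp_ids, "compartment", touched),
                    reaction = untouched(rx_ids, "reaction", touched))
      pools <- pools[vapply(pools, length, 0L) > 0L]
      if (!length(pools)) return(NULL)
      ek <- sample(names(pools), 1L)
      id <- sample(pools[[ek]], 1L)
      pool_name <- switch(ek, species = "species",
                          compartment = "compartments", reaction = "reactions")
      i <- which(entity_ids(m[[pool_name]]) == id)
      e <- m[[pool_name]][[i]]
      attr_name <- sample(c("name", "metaid",
                            if (ek == "species") "initialConcentration"), 1L)
      old <- attr_or_na(e$attributes, attr_name)
      new <- if (is.na(old)) sprintf("v%d", step) else paste0(old, "_v", step)
      e$attributes[[attr_name]] <- new
      if (ek == "species") e <- resync_species(e)
      if (attr_name == "name") e$name <- new
      m[[pool_name]][[i]] <- e
      list(model = m, touched = paste0(ek, ":", id),
           log = log_row("update_attribute", ek, id, attr_name, old, new))
    },
    add_compartment = {
      id <- sprintf("added_comp_%d", step)
      at <- c(id = id, name = sprintf("added compartment %d", step),
              size = "1")
      m$compartments[[length(m$compartments) + 1L]] <-
        new_compartment(id, name = at[["name"]], attributes = at)
      list(model = m, touched = paste0("compartment:", id),
           log = log_row("add_compartment", "compartment", id))
    },
    delete_compartment = {
      used <- unique(c(
        vapply(m$species, function(s) s$compartment %||% NA_character_, ""),
        vapply(m$reactions, function(r) r$compartment %||% NA_character_, ""),
        vapply(m$compartments, function(cc) cc$parent %||% NA_character_, "")))
      cand <- untouched(setdiff(comp_ids, used), "compartment", touched)
      if (!length(cand)) return(NULL)
      id <- sample(cand, 1L)
      m$compartments[[which(comp_ids == id)]] <- NULL
      list(model = m, touched = paste0("compartment:", id),
           log = log_row("delete_compartment", "compartment", id))
    },
    change_participant_role = {
      cand <- untouched(rx_ids, "reaction", touched)
      cand <- cand[vapply(cand, function(id) {
        r <- model_entity(m, "reaction", id)
        length(r$modifiers) > 0L || length(r$reactants) > 0L
      }, TRUE)]
      if (!length(cand)) return(NULL)
      id <- sample(cand, 1L)
      i <- which(rx_ids == id)
      r <- m$reactions[[i]]
      if (length(r$modifiers)) {           # modifier -> reactant
        j <- sample.int(length(r$modifiers), 1L)
        p <- r$modifiers[[j]]
        r$modifiers[[j]] <- NULL
        at <- c(species = p$species, stoichiometry = "1")
        r$reactants[[length(r$reactants) + 1L]] <-
          new_participant(p$species, "reactant", stoichiometry = 1,
                          attributes = at)
        old_role <- "modifier"; new_role <- "reactant"
      } else {                              # reactant -> modifier
        j <- sample.int(length(r$reactants), 1L)
        p <- r$reactants[[j]]
        r$reactants[[j]] <- NULL
        r$modifiers[[length(r$modifiers) + 1L]] <-
          new_participant(p$species, "modifier",
                          attributes = c(species = p$species))
        old_role <- "reactant"; new_role <- "modifier"
      }
      sp <- p$species
      m$reactions[[i]] <- r
      list(model = m,
           touched = c(paste0("reaction:", id), paste0("species:", sp)),
           log = log_row("change_participant_role", "reaction", id, sp,
                         old_role, new_role))
    },
    add_reaction = {
      avail <- setdiff(sp_ids, character())
      if (length(avail) < 2L) return(NULL)
      id <- sprintf("added_rxn_%d", step)
      picks <- sample(avail, 2L)
      at <- c(id = id, name = sprintf("added reaction %d", step),
              reversible = "false", metaid = sprintf("meta_%s", id))
      part <- function(sp, role) {
        new_participant(sp, role,
                        stoichiometry = if (role == "modifier") NA_real_ else 1,
                        attributes = c(species = sp,
                                       if (role != "modifier") c(stoichiometry = "1")))
      }
      m$reactions[[length(m$reactions) + 1L]] <-
        new_reaction(id, name = at[["name"]], reversible = FALSE,
                     reactants = list(part(picks[1L], "reactant")),
                     products = list(part(picks[2L], "product")),
                     attributes = at)
      list(model = m, touched = paste0("reaction:", id),
           log = log_row("add_reaction", "reaction", id))
    },
    delete_reaction = {
      cand <- untouched(rx_ids, "reaction", touched)
      if (!length(cand)) return(NULL)
      id <- sample(cand, 1L)
      m$reactions[[which(rx_ids == id)]] <- NULL
      list(model = m, touched = paste0("reaction:", id),
           log = log_row("delete_reaction", "reaction", id))
    },
    edit_kinetic_law = {
      cand <- untouched(rx_ids, "reaction", touched)
      cand <- cand[vapply(cand, function(id) {
        !is.null(model_entity(m, "reaction", id)$kinetic_law)
      }, TRUE)]
      if (!length(cand)) return(NULL)
      id <- sample(cand, 1L)
      i <- which(rx_ids == id)
      r <- m$reactions[[i]]
      old_txt <- math_to_infix(r$kinetic_law$math)
      r$kinetic_law$math <- math_node("math", children = list(
        math_node("apply", children = list(
          math_node("times"),
          math_node("ci", text = "k1"),
          math_node("cn", text = sprintf("%d", step + 1L))
        ))
      ))
      m$reactions[[i]] <- r
      list(model = m, touched = paste0("reaction:", id),
           log = log_row("edit_kinetic_law", "reaction", id, "math",
                         old_txt, math_to_infix(r$kinetic_law$math)))
    },
    move_element = {
      # permute sibling order only: swap two adjacent untouched species
      cand <- untouched(sp_ids, "species", touched)
      if (length(m$species) < 2L || length(cand) < 2L) return(NULL)
      idx <- which(sp_ids %in% cand)
      adj_start <- idx[(idx + 1L) %in% idx]
      if (!length(adj_start)) return(NULL)
      j <- if (length(adj_start) == 1L) adj_start else {
        adj_start[sample.int(length(adj_start), 1L)]
      }
      tmp <- m$species[[j]]
      m$species[[j]] <- m$species[[j + 1L]]
      m$species[[j + 1L]] <- tmp
      ids <- c(m$species[[j]]$id, m$species[[j + 1L]]$id)
      list(model = m,
           touched = paste0("species:", ids),
           log = log_row("move_element", "species", ids[2L], "sibling_order",
                         old = ids[2L], new = ids[1L]))
    },
    NULL
  )
}

#' Expected change classes implied by a mutation log
#'
#' Replays the log's semantics: added entities are inserts, deleted ones
#' deletes, attribute / participant / kinetic-law edits are updates, and
#' sibling-order moves keep class none. Used as the ground-truth oracle when
#' validating the diff engine against generated fixtures.
#'
#' @param fp a `fixture_pair`
#' @return named character vector, `kind:id` -> expected class
#' @export
mutation_log_classes <- function(fp) {
  stopifnot(inherits(fp, "fixture_pair"))
  out <- character()
  for (i in seq_len(nrow(fp$log))) {
    r <- fp$log[i, ]
    key <- paste0(r$entity_kind, ":", r$subject)
    out[[key]] <- switch(r$kind,
      add_species = , add_compartment = , add_reaction = "insert",
      delete_species = , delete_compartment = , delete_reaction = "delete",
      update_attribute = , change_participant_role = ,
      edit_kinetic_law = "update",
      move_element = "none")
    if (r$kind == "change_participant_role") {
      # the species keeps its own class; only the reaction updates
    }
  }
  out
}
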