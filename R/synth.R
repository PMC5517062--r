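#' Built-in synthetic vocabularies
#'
#' Per-class vocabulary tables used by the corpus generator: reference
#' drugs with ATC codes, experimental stimuli (with their procedure
#' trigger), phenotypic readouts and disease strains for each of the five
#' most common therapeutic groups, plus general-purpose strains and
#' administration details shared across classes. Names are drawn from
#' entities common in rodent pharmacology so fixtures read realistically.
#'
#' @return nested list: one element per class label of the five-class
#'   problem plus `general`.
#' @export
synthetic_vocab <- function() {
  cls <- list(
    antiepileptics = list(
      drugs = data.frame(
        compound_id = c("DRUG_PHT", "DRUG_CBZ", "DRUG_VPA", "DRUG_ESM", "DRUG_PB"),
        name = c("phenytoin", "carbamazepine", "valproic acid",
                 "ethosuximide", "phenobarbital"),
        atc = c("N03AB02", "N03AF01", "N03AG01", "N03AD01", "N03AA02"),
        stringsAsFactors = FALSE),
      stimuli = data.frame(
        stimulus = c("maximal electroshock", "pentylenetetrazole",
                     "bicuculline", "picrotoxin"),
        trigger = "induced", stringsAsFactors = FALSE),
      phenotypes = c("clonic seizures", "tonic convulsions", "seizure latency"),
      strains = c("Wistar", "Swiss")),
    psycholeptics = list(
      drugs = data.frame(
        compound_id = c("DRUG_DZP", "DRUG_HAL", "DRUG_CLZ", "DRUG_CPZ", "DRUG_RIS"),
        name = c("diazepam", "haloperidol", "clozapine", "chlorpromazine",
                 "risperidone"),
        atc = c("N05BA01", "N05AD01", "N05AH02", "N05AA01", "N05AX08"),
        stringsAsFactors = FALSE),
      stimuli = data.frame(
        stimulus = c("apomorphine", "amphetamine", "pentobarbital"),
        trigger = "induced", stringsAsFactors = FALSE),
      phenotypes = c("catalepsy", "locomotor activity", "stereotypic behavior"),
      strains = c("Wistar", "Swiss")),
    antineoplastics = list(
      drugs = data.frame(
        compound_id = c("DRUG_ARA", "DRUG_DOX", "DRUG_MMC", "DRUG_5FU"),
        name = c("cytarabine", "doxorubicin", "mitomycin", "fluorouracil"),
        atc = c("L01BC01", "L01DB01", "L01DC03", "L01BC02"),
        stringsAsFactors = FALSE),
      stimuli = data.frame(
        stimulus = c("P388 leukemia", "L1210 leukemia", "B16 melanoma",
                     "Lewis lung carcinoma"),
        trigger = "implanted", stringsAsFactors = FALSE),
      phenotypes = c("tumor growth", "survival time", "body weight"),
      strains = c("BALB/c", "C57BL", "AKR")),
    antidiabetics = list(
      drugs = data.frame(
        compound_id = c("DRUG_MET", "DRUG_RSG", "DRUG_GLY", "DRUG_TOL"),
        name = c("metformin", "rosiglitazone", "glyburide", "tolrestat"),
        atc = c("A10BA02", "A10BG02", "A10BB01", "A10XA01"),
        stringsAsFactors = FALSE),
      stimuli = data.frame(
        stimulus = c("streptozotocin", "alloxan", "high-fat diet"),
        trigger = c("induced", "induced", "fed"), stringsAsFactors = FALSE),
      phenotypes = c("blood glucose level", "plasma insulin level",
                     "glucose tolerance"),
      strains = c("ZDF", "Zucker", "ob/ob", "db/db")),
    anti_inflammatory = list(
      drugs = data.frame(
        compound_id = c("DRUG_IND", "DRUG_PBZ", "DRUG_KET", "DRUG_ROF"),
        name = c("indomethacin", "phenylbutazone", "ketoprofen", "rofecoxib"),
        atc = c("C01EB03;M01AB01;M02AA23;S01BC01", "M01AA01", "M01AE03",
                "M01AH02"),
        stringsAsFactors = FALSE),
      stimuli = data.frame(
        stimulus = c("carrageenan", "Freund's complete adjuvant",
                     "acetic acid", "TPA"),
        trigger = "induced", stringsAsFactors = FALSE),
      phenotypes = c("paw oedema", "arthritis", "hyperalgesia"),
      strains = c("Sprague Dawley", "Wistar")))
  general <- list(
    strains = c("Wistar", "Sprague Dawley", "Swiss"),
    strain_species = c(
      "Wistar" = "rat", "Sprague Dawley" = "rat", "ZDF" = "rat",
      "Zucker" = "rat", "SHR" = "rat",
      "Swiss" = "mouse", "BALB/c" = "mouse", "C57BL" = "mouse",
      "AKR" = "mouse", "ob/ob" = "mouse", "db/db" = "mouse", "NOD" = "mouse"),
    strain_type = c(
      "Wistar" = "outbred", "Sprague Dawley" = "outbred", "ZDF" = "inbred",
      "Zucker" = "inbred", "SHR" = "inbred",
      "Swiss" = "outbred", "BALB/c" = "inbred", "C57BL" = "inbred",
      "AKR" = "inbred", "ob/ob" = "other", "db/db" = "other", "NOD" = "inbred"),
    strain_synonyms = list(
      "C57BL" = c("Black 6", "C57black", "C56BL/6J"),
      "ob/ob" = c("ob-ob"),
      "NOD" = c("non obese diabetic"),
      "Sprague Dawley" = c("Sprague-Dawley")),
    strain_substrains = list(
      "C57BL" = c("C57BL/6J", "C57BL/6N"),
      "BALB/c" = c("BALB/cJ", "BALB/cByJ"),
      "AKR" = c("AKR/NCr", "AKR/J")),
    effects = c("Inhibition", "Reduction", "Suppression"),
    effect_synonyms = c("Inhibition" = "Attenuation"),
    routes = c("subcutaneous", "intraperitoneal", "oral", "intravenous"),
    route_acronyms = c("subcutaneous" = "sc", "intraperitoneal" = "ip",
                       "oral" = "po", "intravenous" = "iv"),
    transgenes = c("APOA1", "APOE", "LEPR"),
    stimulus_synonyms = c("pentylenetetrazole" = "PTZ",
                          "maximal electroshock" = "maximum electric shock"))
  c(cls, list(general = general))
}

#' Synthetic-corpus configuration
#'
#' Describes the world the generator emits: document and assay counts,
#' class mix, vocabulary tables, and noise knobs. All randomness derives
#' from the mandatory seed, so a configuration is fully reproducible.
#'
#' @param seed integer seed (mandatory).
#' @param n_documents number of source documents (default 100).
#' @param assays_per_document inclusive range, default `c(3, 6)`; assays of
#'   one document share class, template and entities, differing in dose,
#'   route and timing (the near-duplicate structure that motivates
#'   document-based cross-validation splits).
#' @param class_mix named probabilities over the five class labels
#'   (default uniform); must sum to 1.
#' @param vocab vocabulary tables; see [synthetic_vocab()].
#' @param vocab_overlap probability in `[0, 1]` that a document's stimulus
#'   and phenotype are drawn from the pooled vocabulary of all classes
#'   instead of its own class (0 = fully separable class vocabularies,
#'   1 = identical vocabularies, i.e. no signal).
#' @param synonym_plant_rate probability that a description uses the
#'   planted synonym surface form of its effect word / stimulus.
#' @param strain_synonym_rate probability that a strain is written with a
#'   nonstandard synonym or substrain surface form.
#' @param acronym_rate probability that the administration route is written
#'   as its acronym (undone by description normalization).
#' @param hyphen_rate probability that stimulus and trigger are joined by a
#'   hyphen rather than a space (a punctuation variant, not noise: spans
#'   stay consistent either way).
#' @param transgenic_rate probability that a document uses a transgenic
#'   animal instead of a genetic strain.
#' @param general_strain_rate probability that a document uses a
#'   general-purpose strain rather than a class-specific one.
#' @param n_novel_compounds range of additional unapproved compounds tested
#'   per assay.
#' @return a `vm_synth_config` list.
#' @export
synthetic_config <- function(seed,
                             n_documents = 100L,
                             assays_per_document = c(3L, 6L),
                             class_mix = NULL,
                             vocab = synthetic_vocab(),
                             vocab_overlap = 0,
                             synonym_plant_rate = 0,
                             strain_synonym_rate = 0,
                             acronym_rate = 0,
                             hyphen_rate = 0.5,
                             transgenic_rate = 0,
                             general_strain_rate = 0.25,
                             n_novel_compounds = c(0L, 2L)) {
  if (missing(seed)) stop("seed is mandatory")
  labels <- setdiff(names(vocab), "general")
  if (is.null(class_mix)) {
    class_mix <- stats::setNames(rep(1 / length(labels), length(labels)), labels)
  }
  if (abs(sum(class_mix) - 1) > 1e-8) stop("class_mix must sum to 1")
  if (!all(names(class_mix) %in% labels)) stop("class_mix names must be class labels")
  for (l in labels) {
    if (!nrow(vocab[[l]]$drugs) || !nrow(vocab[[l]]$stimuli) ||
        !length(vocab[[l]]$phenotypes)) {
      stop("infeasible config: class '", l, "' has an empty vocabulary")
    }
  }
  structure(list(seed = as.integer(seed), n_documents = as.integer(n_documents),
                 assays_per_document = as.integer(assays_per_document),
                 class_mix = class_mix, vocab = vocab,
                 vocab_overlap = vocab_overlap,
                 synonym_plant_rate = synonym_plant_rate,
                 strain_synonym_rate = strain_synonym_rate,
                 acronym_rate = acronym_rate, hyphen_rate = hyphen_rate,
                 transgenic_rate = transgenic_rate,
                 general_strain_rate = general_strain_rate,
                 n_novel_compounds = as.integer(n_novel_compounds)),
            class = "vm_synth_config")
}

# assemble segments into (text, gold mention table)
vm_assemble <- function(segments) {
  text <- ""
  gold <- list()
  for (seg in segments) {
    if (nzchar(text) && !isTRUE(seg$glue)) text <- paste0(text, " ")
    start <- nchar(text)
    text <- paste0(text, seg$text)
    if (!is.null(seg$class)) {
      gold[[length(gold) + 1L]] <- data.frame(
        entity_class = seg$class, start = start, end = nchar(text) - seg$trim,
        normalized = seg$normalized, stringsAsFactors = FALSE)
    }
  }
  men <- if (length(gold)) do.call(rbind, gold) else
    data.frame(entity_class = character(), start = integer(), end = integer(),
               normalized = character(), stringsAsFactors = FALSE)
  men$surface <- substring(text, men$start + 1L, men$end)
  list(text = text, mentions = men)
}

seg <- function(text, class = NULL, normalized = NULL, glue = FALSE, trim = 0L) {
  list(text = text, class = class, normalized = normalized, glue = glue,
       trim = trim)
}

#' Render one synthetic assay description
#'
#' Assembles a 10-30 word curator-style description of the form
#' "Inhibition of carrageenan-induced paw oedema in Sprague Dawley rat at
#' 5.16 mg/kg, subcutaneous after 3 hrs" from the document-level template
#' parameters, recording gold character spans for every inserted entity.
#'
#' @param params list with elements `effect`, `stimulus`, `trigger`,
#'   `phenotype`, `strain` (or `transgene`), `species`, `template`, plus
#'   surface-form choices made by the caller (`strain_surface`,
#'   `stimulus_surface`, `effect_surface`, `hyphen`, `route`,
#'   `route_surface`, `dose`, `time`).
#' @return list `text`, `mentions` (gold spans in emitted-text coordinates:
#'   `entity_class`, `start`, `end`, `normalized`, `surface`).
#' @export
render_description <- function(params) {
  p <- params
  sepch <- if (isTRUE(p$hyphen)) "-" else " "
  model_txt <- paste0(p$stimulus_surface, sepch, p$trigger)
  model_norm <- paste(p$stimulus, p$trigger)
  animal <- if (!is.null(p$transgene)) {
    # "APOA1 transgenic mouse": gold span excludes the species word
    seg(paste(p$transgene, "transgenic", p$species), class = "transgenic_model",
        normalized = paste(p$transgene, "transgenic"),
        trim = nchar(p$species) + 1L)
  } else {
    seg(paste(p$strain_surface, p$species), class = "genetic_strain",
        normalized = paste(p$strain, p$species))
  }
  segs <- switch(p$template,
    a = list(
      seg(p$effect_surface), seg("of"),
      seg(model_txt, class = "experimental_model", normalized = model_norm),
      seg(p$phenotype, class = "phenotype", normalized = p$phenotype),
      seg("in"), animal,
      seg(paste("at", p$dose, "mg/kg,")),
      seg(p$route_surface),
      seg(paste("after", p$time, "hrs"))),
    b = list(
      seg(p$effect_surface), seg("of"),
      seg(p$phenotype, class = "phenotype", normalized = p$phenotype),
      seg("in"),
      seg(model_txt, class = "experimental_model", normalized = model_norm),
      animal,
      seg(paste("at", p$dose, "mg/kg,")),
      seg(p$route_surface),
      seg(paste("after", p$time, "hrs"))))
  vm_assemble(segs)
}

#' Generate a synthetic assay corpus with gold annotations
#'
#' Emits the full set of artifacts the pipeline consumes: an assay table,
#' a compound table (reference drugs with ATC codes plus unannotated novel
#' compounds), an assay-compound link table, gold annotations (one
#' annotated description per assay, BRAT-compatible via [write_brat()]),
#' and a generator ledger recording every planted truth. Assays of one
#' document share class and entities, reproducing the near-duplicate
#' structure of curated assay data.
#'
#' @param config a [synthetic_config()].
#' @return list `assays`, `compounds`, `links`, `gold`, `ledger`, `config`.
#' @export
generate_corpus <- function(config) {
  stopifnot(inherits(config, "vm_synth_config"))
  v <- config$vocab
  gen <- v$general
  labels <- names(config$class_mix)
  pooled_stimuli <- do.call(rbind, lapply(labels, function(l) v[[l]]$stimuli))
  pooled_stimuli <- pooled_stimuli[!duplicated(pooled_stimuli$stimulus), ]
  pooled_phenos <- unique(unlist(lapply(labels, function(l) v[[l]]$phenotypes)))

  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv())
  })
  set.seed(config$seed)

  assays <- list(); gold <- list(); links <- list(); ledger <- list()
  novel_counter <- 0L
  aid_counter <- 0L
  rint <- function(lo, hi) if (lo >= hi) lo else sample(lo:hi, 1L)

  for (d in seq_len(config$n_documents)) {
    doc_id <- sprintf("DOC%04d", d)
    cls <- sample(labels, 1L, prob = config$class_mix)
    cv <- v[[cls]]
    pooled <- stats::runif(1) < config$vocab_overlap
    st_tab <- if (pooled) pooled_stimuli else cv$stimuli
    si <- rint(1L, nrow(st_tab))
    stimulus <- st_tab$stimulus[si]; trigger <- st_tab$trigger[si]
    phenotype <- if (pooled) sample(pooled_phenos, 1L) else sample(cv$phenotypes, 1L)
    pooled_strains <- unique(unlist(lapply(labels, function(l) v[[l]]$strains)))
    transgenic <- stats::runif(1) < config$transgenic_rate
    if (transgenic) {
      strain <- NA_character_
      transgene <- sample(gen$transgenes, 1L)
      species <- sample(c("mouse", "rat"), 1L)
    } else {
      transgene <- NULL
      pool <- if (pooled) pooled_strains
              else if (stats::runif(1) < config$general_strain_rate) gen$strains
              else cv$strains
      strain <- sample(pool, 1L)
      species <- unname(gen$strain_species[strain])
    }
    drug_i <- rint(1L, nrow(cv$drugs))
    template <- sample(c("a", "b"), 1L)
    effect <- sample(gen$effects, 1L)

    n_assays <- rint(config$assays_per_document[1], config$assays_per_document[2])
    for (a in seq_len(n_assays)) {
      aid_counter <- aid_counter + 1L
      aid <- sprintf("ASSAY%05d", aid_counter)
      effect_surface <- effect
      if (!is.na(gen$effect_synonyms[effect]) &&
          stats::runif(1) < config$synonym_plant_rate) {
        effect_surface <- unname(gen$effect_synonyms[effect])
      }
      stimulus_surface <- stimulus
      if (!is.na(gen$stimulus_synonyms[stimulus]) &&
          stats::runif(1) < config$synonym_plant_rate) {
        stimulus_surface <- unname(gen$stimulus_synonyms[stimulus])
      }
      strain_surface <- strain
      if (!transgenic) {
        syns <- gen$strain_synonyms[[strain]]
        subs <- gen$strain_substrains[[strain]]
        alts <- c(syns, subs)
        if (length(alts) && stats::runif(1) < config$strain_synonym_rate) {
          strain_surface <- sample(alts, 1L)
        }
      }
      route <- sample(gen$routes, 1L)
      route_surface <- if (stats::runif(1) < config$acronym_rate)
        unname(gen$route_acronyms[route]) else route
      dose <- signif(10^stats::runif(1, -1, 2), 3)
      timev <- sample(c(1L, 2L, 3L, 4L, 6L, 8L, 24L), 1L)
      params <- list(effect = effect, effect_surface = effect_surface,
                     stimulus = stimulus, stimulus_surface = stimulus_surface,
                     trigger = trigger, phenotype = phenotype,
                     strain = strain, strain_surface = strain_surface,
                     transgene = transgene, species = species,
                     template = template,
                     hyphen = stats::runif(1) < config$hyphen_rate,
                     route = route, route_surface = route_surface,
                     dose = format(dose, scientific = FALSE), time = timev)
      rd <- render_description(params)
      assays[[aid_counter]] <- data.frame(
        assay_id = aid, description = rd$text, species = species,
        document_id = doc_id, stringsAsFactors = FALSE)
      gold[[aid_counter]] <- list(doc_id = aid, text = rd$text,
                                  mentions = rd$mentions)
      n_novel <- rint(config$n_novel_compounds[1], config$n_novel_compounds[2])
      novel_ids <- if (n_novel > 0) {
        sprintf("NOVEL%05d", novel_counter + seq_len(n_novel))
      } else character()
      novel_counter <- novel_counter + n_novel
      links[[aid_counter]] <- data.frame(
        assay_id = aid,
        compound_id = c(cv$drugs$compound_id[drug_i], novel_ids),
        stringsAsFactors = FALSE)
      ledger[[aid_counter]] <- data.frame(
        assay_id = aid, document_id = doc_id, class = cls,
        drug_id = cv$drugs$compound_id[drug_i],
        model = paste(stimulus, trigger),
        phenotype = phenotype,
        strain = if (transgenic) NA_character_ else paste(strain, species),
        transgene = if (transgenic) paste(transgene, "transgenic") else NA_character_,
        pooled_vocab = pooled, stringsAsFactors = FALSE)
    }
  }
  assay_tab <- do.call(rbind, assays)
  link_tab <- do.call(rbind, links)
  cid <- split(link_tab$compound_id, link_tab$assay_id)
  assay_tab$compound_ids <- unname(cid[assay_tab$assay_id])
  drug_tab <- do.call(rbind, lapply(labels, function(l) v[[l]]$drugs))
  drug_tab <- drug_tab[!duplicated(drug_tab$compound_id), ]
  compounds <- data.frame(
    compound_id = c(drug_tab$compound_id,
                    sprintf("NOVEL%05d", seq_len(novel_counter))),
    name = c(drug_tab$name, rep(NA_character_, novel_counter)),
    max_phase = c(rep(4L, nrow(drug_tab)), rep(0L, novel_counter)),
    stringsAsFactors = FALSE)
  compounds$atc_codes <- c(strsplit(drug_tab$atc, ";", fixed = TRUE),
                           rep(list(character()), novel_counter))
  list(assays = assay_tab, compounds = compounds, links = link_tab,
       gold = gold, ledger = do.call(rbind, ledger), config = config)
}

#' Strain listing table matching the synthetic vocabulary
#'
#' Produces, for one species, the listing-table layout consumed by
#' [compile_strain_dictionary()], covering every strain the generator can
#' emit (with its synonyms and substrains), so that lexicons compiled from
#' it recognize all planted strain mentions.
#'
#' @param species `"mouse"` or `"rat"`.
#' @param vocab vocabulary list from [synthetic_vocab()].
#' @return data.frame `name`, `type`, `synonyms`, `substrains`.
#' @export
synth_strain_listing <- function(species = c("mouse", "rat"),
                                 vocab = synthetic_vocab()) {
  species <- match.arg(species)
  gen <- vocab$general
  strains <- names(gen$strain_species)[gen$strain_species == species]
  data.frame(
    name = strains,
    type = unname(gen$strain_type[strains]),
    synonyms = vapply(strains, function(s)
      paste(gen$strain_synonyms[[s]], collapse = ";"), ""),
    substrains = vapply(strains, function(s)
      paste(gen$strain_substrains[[s]], collapse = ";"), ""),
    stringsAsFactors = FALSE)
}

#' Write a phenotype ontology matching the synthetic vocabulary
#'
#' Writes a small synthetic OBO file containing one term per phenotype the
#' generator can emit, so a phenotype dictionary built from it recognizes
#' every planted phenotype mention.
#'
#' @param path output OBO path.
#' @param vocab vocabulary list from [synthetic_vocab()].
#' @return `path`, invisibly.
#' @export
synth_phenotype_obo <- function(path, vocab = synthetic_vocab()) {
  labels <- setdiff(names(vocab), "general")
  phenos <- sort(unique(unlist(lapply(labels, function(l) vocab[[l]]$phenotypes))))
  lines <- c("format-version: 1.2", "ontology: synthpheno", "")
  for (i in seq_along(phenos)) {
    lines <- c(lines, "[Term]",
               sprintf("id: SYNPH:%07d", i),
               sprintf("name: %s", phenos[i]), "")
  }
  writeLines(lines, path)
  invisible(path)
}

#' Convenience: lexicons for a synthetic corpus
#'
#' Compiles the mouse/rat strain dictionaries and the phenotype dictionary
#' that exactly cover the generator's vocabulary.
#'
#' @param vocab vocabulary list from [synthetic_vocab()].
#' @return a [vm_pipeline()] with all three dictionaries set.
#' @export
synth_pipeline <- function(vocab = synthetic_vocab()) {
  obo <- tempfile(fileext = ".obo")
  synth_phenotype_obo(obo, vocab)
  on.exit(unlink(obo))
  vm_pipeline(
    mouse_dict = compile_strain_dictionary(synth_strain_listing("mouse", vocab), "mouse"),
    rat_dict = compile_strain_dictionary(synth_strain_listing("rat", vocab), "rat"),
    pheno_dict = load_phenotype_dictionary(obo))
}
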