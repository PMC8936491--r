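test_that("identical files map every entity with no change", {
  m <- read_sbml(xy_model())
  em <- map_entities(m, m)
  expect_identical(nrow(em$matched), 4L)   # 1 compartment + 2 species + 1 reaction
  expect_identical(nrow(em$only_in_a), 0L)
  expect_identical(nrow(em$only_in_b), 0L)
  cs <- classify(m, m)
  expect_true(all(cs$class_of == "none"))
  expect_true(all(vapply(cs$records_of, nrow, 0L) == 0L))
})

test_that("entities sharing an id are matched, never delete+insert", {
  a <- read_sbml(sbml_doc(paste0(
    '    <listOfCompartments><compartment id="c"/></listOfCompartments>\n',
    '    <listOfSpecies><species id="s" name="old" compartment="c"/></listOfSpecies>\n')))
  b <- read_sbml(sbml_doc(paste0(
    '    <listOfCompartments><compartment id="c"/></listOfCompartments>\n',
    '    <listOfSpecies><species id="s" name="new" compartment="c" constant="true"/></listOfSpecies>\n')))
  em <- map_entities(a, b)
  expect_true(any(em$matched$id_a == "s" & em$matched$id_b == "s"))
  expect_identical(nrow(em$only_in_a), 0L)
  expect_identical(nrow(em$only_in_b), 0L)
  cs <- classify(a, b)
  expect_identical(cs$class_of[["species:s"]], "update")
})

test_that("unmatched ids fall back to unique-name matching", {
  a <- read_sbml(sbml_doc(paste0(
    '    <listOfSpecies><species id="s_v1" name="calcium"/></listOfSpecies>\n')))
  b <- read_sbml(sbml_doc(paste0(
    '    <listOfSpecies><species id="s_v2" name="calcium"/></listOfSpecies>\n')))
  em <- map_entities(a, b)
  expect_identical(nrow(em$matched), 1L)
  expect_identical(em$matched$id_a, "s_v1")
  expect_identical(em$matched$id_b, "s_v2")
})

test_that("attribute diffs report adds, deletes and updates but never order", {
  mk <- function(attrs) {
    list(id = "s", attributes = attrs, path = "/sbml/model/species[1]")
  }
  a <- mk(c(id = "s", name = "Ca", compartment = "cyt"))
  b <- mk(c(id = "s", name = "Calcium", compartment = "er",
            initialConcentration = "0.1", constant = "false"))
  recs <- diff_attributes(a, b)
  upd <- recs[recs$verb == "updated", ]
  expect_setequal(upd$subject, c("name", "compartment"))
  expect_setequal(recs$subject[recs$verb == "added"],
                  c("initialConcentration", "constant"))
  # identity and pure reorder both produce nothing
  expect_identical(nrow(diff_attributes(a, a)), 0L)
  b2 <- mk(rev(a$attributes))
  expect_identical(nrow(diff_attributes(a, b2)), 0L)
})

test_that("participant role changes yield one deleted plus one added record", {
  a <- read_sbml(sbml_doc(paste0(
    '    <listOfSpecies><species id="ADP"/><species id="BPG"/><species id="ATP"/></listOfSpecies>\n',
    '    <listOfReactions><reaction id="r">\n',
    '      <listOfReactants><speciesReference species="BPG"/></listOfReactants>\n',
    '      <listOfProducts><speciesReference species="ATP"/></listOfProducts>\n',
    '      <listOfModifiers><modifierSpeciesReference species="ADP"/></listOfModifiers>\n',
    "    </reaction></listOfReactions>\n")))
  b <- read_sbml(sbml_doc(paste0(
    '    <listOfSpecies><species id="ADP"/><species id="BPG"/><species id="ATP"/></listOfSpecies>\n',
    '    <listOfReactions><reaction id="r">\n',
    '      <listOfReactants><speciesReference species="BPG"/>',
    '<speciesReference species="ADP"/></listOfReactants>\n',
    '      <listOfProducts><speciesReference species="ATP"/></listOfProducts>\n',
    "    </reaction></listOfReactions>\n")))
  ra <- a$reactions[[1]]; rb <- b$reactions[[1]]
  recs <- diff_participants(ra, rb)
  expect_identical(nrow(recs), 2L)
  expect_identical(recs$verb[grepl("modifier", recs$subject)], "deleted")
  expect_identical(recs$verb[grepl("reactant", recs$subject) &
                             grepl("ADP", recs$subject)], "added")
  # identity
  expect_identical(nrow(diff_participants(ra, ra)), 0L)
})

test_that("removing one reactant yields exactly the records of a set diff", {
  # oracle: exhaustive comparison of (species, role) pairs
  mk_rxn <- function(reactants) {
    read_sbml(sbml_doc(paste0(
      "    <listOfSpecies>",
      paste(sprintf('<species id="s%d"/>', 1:4), collapse = ""),
      "</listOfSpecies>\n",
      '    <listOfReactions><reaction id="r">\n',
      "      <listOfReactants>",
      paste(sprintf('<speciesReference species="%s"/>', reactants),
            collapse = ""),
      "</listOfReactants>\n",
      '      <listOfProducts><speciesReference species="s4"/></listOfProducts>\n',
      "    </reaction></listOfReactions>\n")))$reactions[[1]]
  }
  ra <- mk_rxn(c("s1", "s2", "s3"))
  rb <- mk_rxn(c("s1", "s3"))
  oracle <- setdiff(paste(c("s1", "s2", "s3"), "reactant"),
                    paste(c("s1", "s3"), "reactant"))
  recs <- diff_participants(ra, rb)
  expect_identical(nrow(recs), length(oracle))
  expect_identical(recs$verb, "deleted")
  expect_match(recs$subject, "s2")
})

test_that("kinetic laws are compared structurally, not textually", {
  law_xml <- function(ws) sbml_doc(paste0(
    '    <listOfSpecies><species id="S"/></listOfSpecies>\n',
    '    <listOfReactions><reaction id="r">\n',
    '      <listOfProducts><speciesReference species="S"/></listOfProducts>\n',
    "      <kineticLaw>\n",
    '        <math xmlns="http://www.w3.org/1998/Math/MathML">',
    ws, "<apply><times/>", ws, "<ci>k</ci><ci>S</ci></apply>", ws, "</math>\n",
    "      </kineticLaw>\n    </reaction></listOfReactions>\n"))
  la <- read_sbml(law_xml(""))$reactions[[1]]$kinetic_law
  lb <- read_sbml(law_xml("\n   "))$reactions[[1]]$kinetic_law
  expect_identical(nrow(diff_kinetic_law(la, lb)), 0L)

  # law present only on one side
  one <- diff_kinetic_law(NULL, lb)
  expect_identical(one$verb, "added")
  expect_identical(one$subject_kind, "kinetic_law")

  # hand-built three-node trees differing in one operand constant
  t_old <- sbgndiff:::math_node("math", children = list(
    sbgndiff:::math_node("apply", children = list(
      sbgndiff:::math_node("times"),
      sbgndiff:::math_node("ci", text = "k"),
      sbgndiff:::math_node("cn", text = "2")))))
  t_new <- sbgndiff:::math_node("math", children = list(
    sbgndiff:::math_node("apply", children = list(
      sbgndiff:::math_node("times"),
      sbgndiff:::math_node("ci", text = "k"),
      sbgndiff:::math_node("cn", text = "3")))))
  expect_false(sbgndiff:::math_equal(t_old, t_new))   # direct-tree oracle
  recs <- diff_kinetic_law(list(math = t_old, local_parameters = list()),
                           list(math = t_new, local_parameters = list()))
  expect_identical(nrow(recs), 1L)
  expect_identical(recs$verb, "updated")
  expect_identical(recs$old, "(k * 2)")
  expect_identical(recs$new, "(k * 3)")
})

test_that("classification recovers a hand-written mutation scenario", {
  # 2 species updates, 1 compartment insert, 1 reaction participant change
  a <- read_sbml(sbml_doc(paste0(
    '    <listOfCompartments><compartment id="c1"/></listOfCompartments>\n',
    '    <listOfSpecies>\n',
    '      <species id="s1" name="one" compartment="c1"/>\n',
    '      <species id="s2" name="two" compartment="c1"/>\n',
    '      <species id="s3" name="three" compartment="c1"/>\n',
    "    </listOfSpecies>\n",
    '    <listOfReactions><reaction id="r1">\n',
    '      <listOfReactants><speciesReference species="s1"/></listOfReactants>\n',
    '      <listOfProducts><speciesReference species="s2"/></listOfProducts>\n',
    '      <listOfModifiers><modifierSpeciesReference species="s3"/></listOfModifiers>\n',
    "    </reaction></listOfReactions>\n")))
  b <- read_sbml(sbml_doc(paste0(
    '    <listOfCompartments><compartment id="c1"/><compartment id="c2"/></listOfCompartments>\n',
    '    <listOfSpecies>\n',
    '      <species id="s1" name="one renamed" compartment="c1"/>\n',
    '      <species id="s2" name="two" compartment="c2"/>\n',
    '      <species id="s3" name="three" compartment="c1"/>\n',
    "    </listOfSpecies>\n",
    '    <listOfReactions><reaction id="r1">\n',
    '      <listOfReactants><speciesReference species="s1"/>',
    '<speciesReference species="s3"/></listOfReactants>\n',
    '      <listOfProducts><speciesReference species="s2"/></listOfProducts>\n',
    "    </reaction></listOfReactions>\n")))
  cs <- classify(a, b)
  expect_identical(cs$class_of[["species:s1"]], "update")
  expect_identical(cs$class_of[["species:s2"]], "update")
  expect_identical(cs$class_of[["species:s3"]], "none")
  expect_identical(cs$class_of[["compartment:c2"]], "insert")
  expect_identical(cs$class_of[["compartment:c1"]], "none")
  expect_identical(cs$class_of[["reaction:r1"]], "update")
})

test_that("diff is symmetric and identity-stable on generated fixtures", {
  for (seed in 1:8) {
    fp <- make_fixture(seed)
    a <- read_sbml(fp$model_a); b <- read_sbml(fp$model_b)
    csab <- classify(a, b); csba <- classify(b, a)
    ins_ab <- names(csab$class_of)[csab$class_of == "insert"]
    del_ba <- names(csba$class_of)[csba$class_of == "delete"]
    expect_setequal(ins_ab, del_ba)
    upd_ab <- names(csab$class_of)[csab$class_of == "update"]
    upd_ba <- names(csba$class_of)[csba$class_of == "update"]
    expect_setequal(upd_ab, upd_ba)
    ident <- classify(a, a)
    expect_true(all(ident$class_of == "none"))
  }
})

test_that("whitespace and attribute reorder leave the change set unchanged", {
  fp <- make_fixture(21)
  a1 <- read_sbml(fp$model_a); b1 <- read_sbml(fp$model_b)
  a2 <- read_sbml(reserialise_shuffled(fp$model_a))
  b2 <- read_sbml(reserialise_shuffled(fp$model_b))
  cs1 <- classify(a1, b1); cs2 <- classify(a2, b2)
  expect_identical(cs1$class_of[order(names(cs1$class_of))],
                   cs2$class_of[order(names(cs2$class_of))])
})

test_that("pure document moves map paths but keep class none", {
  a <- sbml_doc(paste0(
    "    <listOfSpecies>\n",
    '      <species id="p" name="P"/>\n      <species id="q" name="Q"/>\n',
    "    </listOfSpecies>\n"))
  b <- sbml_doc(paste0(
    "    <listOfSpecies>\n",
    '      <species id="q" name="Q"/>\n      <species id="p" name="P"/>\n',
    "    </listOfSpecies>\n"))
  cs <- classify(read_sbml(a), read_sbml(b))
  expect_true(all(cs$class_of == "none"))
  expect_length(cs$move_path_map, 2)
  expect_true(all(names(cs$move_path_map) != cs$move_path_map))
})

test_that("change reports render subject, verb and values in document order", {
  a <- read_sbml(sbml_doc(paste0(
    '    <listOfCompartments><compartment id="cyt"/><compartment id="er"/></listOfCompartments>\n',
    '    <listOfSpecies><species id="ca" name="Calcium" compartment="cyt">',
    "<annotation><x>1</x></annotation></species></listOfSpecies>\n")))
  b <- read_sbml(sbml_doc(paste0(
    '    <listOfCompartments><compartment id="cyt"/><compartment id="er"/></listOfCompartments>\n',
    '    <listOfSpecies><species id="ca" name="Calcium-Cyt" compartment="er" ',
    'initialConcentration="0.3" constant="false">',
    "<annotation><x>2</x></annotation></species></listOfSpecies>\n")))
  cs <- classify(a, b)
  rep <- change_report(cs, "ca")
  expect_setequal(rep$subject[rep$verb == "updated"], c("name", "compartment"))
  expect_setequal(rep$subject[rep$verb == "added"],
                  c("initialConcentration", "constant"))
  # annotation changes are detected (update class) but not displayed
  expect_false(any(rep$subject_kind == "annotation"))
  expect_identical(cs$class_of[["species:ca"]], "update")
  expect_match(rep$text[rep$subject == "name"], "Calcium-Cyt")

  # unchanged entity: empty report; unknown entity: lookup error
  expect_identical(nrow(change_report(cs, "cyt")), 0L)
  expect_error(change_report(cs, "nope"), class = "sbgndiff_lookup_error")
})

test_that("sub-node metaid updates surface in the reaction's report", {
  a <- read_sbml(sbml_doc(paste0(
    '    <listOfSpecies><species id="s1"/><species id="s2"/></listOfSpecies>\n',
    '    <listOfReactions><reaction id="r" metaid="m1">\n',
    '      <listOfReactants><speciesReference species="s1" metaid="p1"/></listOfReactants>\n',
    '      <listOfProducts><speciesReference species="s2"/></listOfProducts>\n',
    "    </reaction></listOfReactions>\n")))
  b <- read_sbml(sbml_doc(paste0(
    '    <listOfSpecies><species id="s1"/><species id="s2"/></listOfSpecies>\n',
    '    <listOfReactions><reaction id="r" metaid="m2">\n',
    '      <listOfReactants><speciesReference species="s1" metaid="p2"/></listOfReactants>\n',
    '      <listOfProducts><speciesReference species="s2"/></listOfProducts>\n',
    "    </reaction></listOfReactions>\n")))
  cs <- classify(a, b)
  rep <- change_report(cs, "r")
  expect_true(any(rep$subject == "metaid" & rep$verb == "updated"))
  expect_true(any(grepl("speciesReference s1", rep$subject)))
  expect_identical(cs$class_of[["reaction:r"]], "update")
})
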