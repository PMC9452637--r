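# Worked example: a point-of-care clinical decision support (CDS) flow for
# thiopurine (6-mercaptopurine) dosing guided by TPMT and NUDT15 genotypes,
# following the CPIC guideline organization (guideline and workflow documents
# are published at https://cpicpgx.org/guidelines/guideline-for-thiopurines-
# and-tpmt/; they are cited here for provenance only and never fetched).
#
# The record wording below is a representative, NON-NORMATIVE paraphrase of
# the published decision flow, written for demonstrating the modelling
# pattern. It is not a clinical source. The record counts are internal
# choices of this fixture, asserted only for self-consistency.

#' Build the thiopurine CDS example knowledgebase
#'
#' Encodes a pharmacogenomic clinical decision support flow in the engine's
#' pattern: one table per category of clinical action. The flow distinguishes
#' three action categories — judgement (a criterion on the patient's state),
#' drug order suggestion, and test alert suggestion — so the entire CDS lives
#' in exactly three tables:
#'
#' * `Judgement`: `criterion` (required text) and `Next`, a polymorphic
#'   reference. Because `Next` can point into any table, a judgement's next
#'   step may be another judgement, a drug order, or a test alert — one field
#'   models the "next step" concept for all of them, and future action
#'   categories plug in with no schema change.
#' * `DrugOrder`: `description` (required text).
#' * `CDSTestAlert`: `alert` (required text).
#'
#' The decision flow is entered blank-then-link: records first, references
#' wired afterwards. Judgement#1 chains to Judgement#2 (a self-table link)
#' and on to DrugOrder#1; the remaining judgements branch to the reduced-dose
#' drug order and to the pre-test alert.
#'
#' @return A knowledgebase that validates clean.
#' @export
build_cds_fixture <- function() {
  kb <- kb_new() |>
    kb_create_table("Judgement", list(
      kb_field("criterion", "TEXT", annotation = "decision criterion on the patient state",
               constraints = list(kb_constraint("required"))),
      kb_field("Next", "REFERENCE", annotation = "next step in the decision flow")
    )) |>
    kb_create_table("DrugOrder", list(
      kb_field("description", "TEXT", annotation = "drug order suggestion",
               constraints = list(kb_constraint("required")))
    )) |>
    kb_create_table("CDSTestAlert", list(
      kb_field("alert", "TEXT", annotation = "test alert suggestion",
               constraints = list(kb_constraint("required")))
    ))

  kb <- kb |>
    kb_insert("Judgement", list(
      criterion = "TPMT and NUDT15 genotype results on file before 6-MP order?")) |>
    kb_insert("Judgement", list(
      criterion = "TPMT and NUDT15 both normal metabolizer status?")) |>
    kb_insert("Judgement", list(
      criterion = "TPMT or NUDT15 intermediate or poor metabolizer status?")) |>
    kb_insert("Judgement", list(
      criterion = "Genotype results not on file at the time of the 6-MP order?")) |>
    kb_insert("DrugOrder", list(
      description = "Proceed with the standard 6-MP starting dose per the disease-specific protocol.")) |>
    kb_insert("DrugOrder", list(
      description = "Reduce the 6-MP starting dose or select an alternative agent per the thiopurine dosing guidance.")) |>
    kb_insert("CDSTestAlert", list(
      alert = "Pre-test alert: order TPMT and NUDT15 genotyping before initiating 6-MP."))

  kb |>
    kb_set_ref("Judgement", 1, "Next", "Judgement", 2) |>
    kb_set_ref("Judgement", 2, "Next", "DrugOrder", 1) |>
    kb_set_ref("Judgement", 3, "Next", "DrugOrder", 2) |>
    kb_set_ref("Judgement", 4, "Next", "CDSTestAlert", 1)
}

#' Build the ITPA extension specification
#'
#' The late-arriving-knowledge scenario: a new genotype test result (inosine
#' triphosphate pyrophosphatase, ITPA) and its therapy become available after
#' the CDS model is in production. Under the polymorphic-reference pattern
#' the change is purely additive — one new `ITPATherapy` table with its
#' therapy record, plus a rewiring of an existing judgement's `Next` into the
#' new branch; no existing table structure or constraint is modified. The
#' specific rewire (the intermediate/poor-metabolizer judgement now leads to
#' the ITPA-informed therapy) is one representative reading of the scenario.
#'
#' @return A `polykb_extension` to apply with [kb_extend()] against
#'   [build_cds_fixture()].
#' @export
build_itpa_extension <- function() {
  kb_extension(
    name = "ITPATherapy",
    fields = list(
      kb_field("specification", "TEXT",
               annotation = "therapy specification informed by the ITPA genotype",
               constraints = list(kb_constraint("required")))
    ),
    records = list(
      list(specification = "Adjust thiopurine therapy for patients carrying a deficient ITPA genotype per the new evidence.")
    ),
    rewires = list(
      list(table = "Judgement", id = 3L, field = "Next",
           target_table = "ITPATherapy", target_id = 1L)
    )
  )
}
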