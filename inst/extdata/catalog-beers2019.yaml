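# Claims-operable PIM rule catalog for older adults (2019 Beers subset).
# Only rules decidable from dispensing data are included: no drug-disease,
# drug-drug interaction tables or renal-dose rules (those need clinical
# data). Ticlopidine is retained although removed from the 2019 update,
# because it remains marketed and reimbursed in Italy.
version: beers2019-claims-1.0
rules:
  - id: amiodarone
    category: AVOID
    label: Amiodarone
    atc: [C01BD01]
    condition: {type: ALWAYS}
    rationale: >
      Greater toxicity than other antiarrhythmics; avoid as first-line
      therapy for atrial fibrillation.
  - id: aspirin_high_dose
    category: AVOID
    label: Aspirin >325 mg/day
    atc: [B01AC06]
    condition: {type: UNIT_DOSE_EXCEEDS, mg_per_day: 325}
    rationale: >
      Doses above 325 mg/day raise gastrointestinal bleeding risk without
      added cardiovascular benefit; unit dose used as daily-dose proxy.
  - id: nsaid_anticoagulant
    category: AVOID
    label: NSAID
    atc: [M01A]
    condition: {type: CO_DISPENSED_WITH, atc: [B01AA], window_days: 90}
    rationale: >
      Non-selective NSAIDs co-dispensed with oral vitamin K antagonists
      within 3 months: increased risk of gastrointestinal bleeding.
  - id: nsaid_chronic
    category: AVOID
    label: NSAID
    atc: [M01A]
    condition: {type: CHRONIC_USE, min_events: 5}
    rationale: >
      Chronic use of non-COX-selective NSAIDs: risk of gastrointestinal
      bleeding and peptic ulcer disease in older adults.
  - id: paroxetine
    category: AVOID
    label: Paroxetine
    atc: [N06AB05]
    condition: {type: ALWAYS}
    rationale: >
      Strongly anticholinergic SSRI; sedation, orthostatic hypotension.
  - id: ppi_over_8_weeks
    category: AVOID
    label: PPI
    atc: [A02BC]
    condition: {type: DURATION_OVER_8_WEEKS, min_gap_days: 56, max_gap_days: 180}
    rationale: >
      Scheduled proton-pump inhibitor use beyond 8 weeks: risk of
      C. difficile infection, fractures, and nutrient malabsorption.
      Operationalized as consecutive dispensations more than 56 days apart
      and within 180 days.
  - id: sulfonylureas
    category: AVOID
    label: Sulfonylureas
    atc: [A10BB]
    condition: {type: ALWAYS}
    rationale: >
      Higher risk of severe prolonged hypoglycemia and SIADH than other
      glucose-lowering agents.
  - id: ticlopidine
    category: AVOID
    label: Ticlopidine
    atc: [B01AC05]
    condition: {type: ALWAYS}
    rationale: >
      Safer, more effective antiplatelet alternatives exist; retained from
      the 2015 criteria for markets where ticlopidine is still reimbursed.
  - id: tricyclic_antidepressants
    category: AVOID
    label: TCA
    atc: [N06AA]
    condition: {type: ALWAYS}
    rationale: >
      Highly anticholinergic, sedating, cause orthostatic hypotension.
  - id: aldosterone_antagonists
    category: CAUTION
    label: Aldosterone antagonists
    atc: [C03DA]
    condition: {type: ALWAYS}
    rationale: Risk of hyperkalemia and hyponatremia in older adults.
  - id: antipsychotics_caution
    category: CAUTION
    label: Antipsychotics
    atc: [N05A]
    condition: {type: ALWAYS}
    rationale: May exacerbate or cause SIADH or hyponatremia.
  - id: diuretic_ksparing_combinations
    category: CAUTION
    label: Minor diuretics + potassium-sparing agents
    atc: [C03EA]
    condition: {type: ALWAYS}
    rationale: >
      Fixed combinations of low-ceiling diuretics and potassium-sparing
      agents; risk of hyponatremia (SIADH).
  - id: furosemide
    category: CAUTION
    label: Furosemide, torsemide
    atc: [C03CA]
    condition: {type: ALWAYS}
    rationale: >
      Loop diuretics may exacerbate or cause SIADH or hyponatremia; monitor
      sodium closely.
  - id: furosemide_ksparing
    category: CAUTION
    label: Furosemide + potassium-sparing agents
    atc: [C03EB]
    condition: {type: ALWAYS}
    rationale: >
      Fixed combinations of high-ceiling diuretics and potassium-sparing
      agents; hyponatremia risk.
  - id: hydrochlorothiazide
    category: CAUTION
    label: Hydrochlorothiazide
    atc: [C03AA03]
    condition: {type: ALWAYS}
    rationale: Thiazide diuretic; hyponatremia and SIADH risk.
  - id: minor_diuretics
    category: CAUTION
    label: Minor diuretics
    atc: [C03BA]
    condition: {type: ALWAYS}
    rationale: Low-ceiling diuretics; hyponatremia and SIADH risk.
  - id: mirtazapine
    category: CAUTION
    label: Mirtazapine
    atc: [N06AX11]
    condition: {type: ALWAYS}
    rationale: May exacerbate or cause SIADH or hyponatremia.
  - id: tramadol
    category: CAUTION
    label: Tramadol
    atc: [N02AX02]
    condition: {type: ALWAYS}
    rationale: May exacerbate or cause SIADH or hyponatremia.
  - id: achol_amitriptyline
    category: ANTICHOLINERGIC
    label: Amitriptyline
    atc: [N06AA09]
    condition: {type: ALWAYS}
    rationale: Strong anticholinergic tricyclic antidepressant.
  - id: achol_clomipramine
    category: ANTICHOLINERGIC
    label: Clomipramine
    atc: [N06AA04]
    condition: {type: ALWAYS}
    rationale: Strong anticholinergic tricyclic antidepressant.
  - id: achol_disopyramide
    category: ANTICHOLINERGIC
    label: Disopyramide
    atc: [C01BA03]
    condition: {type: ALWAYS}
    rationale: Strong anticholinergic class Ia antiarrhythmic.
  - id: achol_hydroxyzine
    category: ANTICHOLINERGIC
    label: Hydroxyzine
    atc: [N05BB01]
    condition: {type: ALWAYS}
    rationale: Strong anticholinergic first-generation antihistamine.
  - id: achol_olanzapine
    category: ANTICHOLINERGIC
    label: Olanzapine
    atc: [N05AH03]
    condition: {type: ALWAYS}
    rationale: Strong anticholinergic atypical antipsychotic.
  - id: achol_oxybutynin
    category: ANTICHOLINERGIC
    label: Oxybutynin
    atc: [G04BD04]
    condition: {type: ALWAYS}
    rationale: Strong anticholinergic urinary antispasmodic.
  - id: achol_paroxetine
    category: ANTICHOLINERGIC
    label: Paroxetine
    atc: [N06AB05]
    condition: {type: ALWAYS}
    rationale: Strong anticholinergic SSRI.
  - id: achol_trihexyphenidyl
    category: ANTICHOLINERGIC
    label: Trihexyphenidyl
    atc: [N04AA01]
    condition: {type: ALWAYS}
    rationale: Strong anticholinergic antiparkinson agent.
# Anticholinergic cognitive burden scores (longest ATC prefix wins).
acb:
  - {atc: C01BA03, score: 3}
  - {atc: G04BD04, score: 3}
  - {atc: N04AA01, score: 3}
  - {atc: N05AH03, score: 3}
  - {atc: N05BB01, score: 3}
  - {atc: N06AA04, score: 3}
  - {atc: N06AA09, score: 3}
  - {atc: N06AB05, score: 3}
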