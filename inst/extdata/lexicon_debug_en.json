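{
  "id": "debug_en",
  "disease_terms": {
    "schizophrenia": "F20",
    "major depressive disorder": "F32",
    "depressive episode": "F32",
    "bipolar disorder": "F31",
    "other nonorganic mental disorder": "F28",
    "unspecified nonorganic psychosis": "F29"
  },
  "kinship_terms": {
    "father": {"relation": "father", "degree": "first"},
    "mother": {"relation": "mother", "degree": "first"},
    "brother": {"relation": "brother", "degree": "first"},
    "sister": {"relation": "sister", "degree": "first"},
    "son": {"relation": "son", "degree": "first"},
    "daughter": {"relation": "daughter", "degree": "first"},
    "grandfather": {"relation": "grandfather", "degree": "second"},
    "grandmother": {"relation": "grandmother", "degree": "second"},
    "aunt": {"relation": "aunt", "degree": "second"},
    "uncle": {"relation": "uncle", "degree": "second"},
    "nephew": {"relation": "nephew", "degree": "second"},
    "niece": {"relation": "niece", "degree": "second"},
    "half-brother": {"relation": "half_brother", "degree": "second"},
    "half-sister": {"relation": "half_sister", "degree": "second"},
    "cousin": {"relation": "cousin", "degree": "third"},
    "great-grandfather": {"relation": "great_grandfather", "degree": "third"},
    "great-grandmother": {"relation": "great_grandmother", "degree": "third"}
  },
  "negation_cues": ["denies", "no history of", "without any"],
  "section_cues": ["FAMILY HISTORY:"],
  "templates": {
    "fh_intro": "FAMILY HISTORY: ",
    "fh_event": "the patient's {kin} had been diagnosed with a {disease}",
    "event_sep": "; ",
    "sentence_end": ".",
    "denial_body": "denies any family history of psychiatric disorder",
    "distractor": "Past workup once raised the question of {disease}.",
    "fillers": [
      "The patient was admitted with low mood lasting one month.",
      "On admission the patient was alert and oriented.",
      "Gradual loss of interest and fatigue over the course of illness.",
      "Premorbid personality described as introverted.",
      "Past medical record otherwise unremarkable.",
      "Appetite and sleep are poor; bowel habits normal.",
      "Physical examination of heart, lungs and abdomen unremarkable.",
      "Recent weight loss and subjective lack of energy."
    ],
    "padding": "Remainder of the record is unchanged; further investigations are planned after admission and the clinical course will be observed. ",
    "wordlist": ["admitted", "admission", "patient", "examination", "history",
                 "diagnosed", "mood", "sleep", "weight", "illness"]
  }
}
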