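{
  "name": "stroop_trial_table",
  "description": "One row per timed response of the color-word matching Stroop task. Three blocks of two 48-trial runs each; music (and hence a tempo) only in block 2; one tempo per participant.",
  "dialect": {
    "encoding": "UTF-8",
    "delimiter": ",",
    "decimal_separator": ".",
    "header": true
  },
  "fields": [
    {"name": "participant_id", "type": "string", "description": "Participant identifier."},
    {"name": "gender", "type": "string", "enum": ["male", "female"]},
    {"name": "phase", "type": "string", "enum": ["menstrual", "folicular", "ovulatory", "luteal", "not_applicable"], "description": "Menstrual-cycle phase (forward-counting); not_applicable for male participants."},
    {"name": "tempo_bpm", "type": "integer", "enum": [100, 140, 180], "nullable": true, "description": "Tempo of the acoustic rhythm; empty outside block 2."},
    {"name": "block", "type": "integer", "enum": [1, 2, 3]},
    {"name": "run", "type": "string", "enum": ["neutral", "stroop"]},
    {"name": "congruent", "type": "integer", "enum": [0, 1], "description": "Whether word and color agreed in the trial."},
    {"name": "rt_s", "type": "number", "exclusiveMinimum": 0, "description": "Reaction time in seconds."}
  ]
}
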