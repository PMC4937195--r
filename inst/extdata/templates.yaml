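# Algorithm-template catalogue (user-editable stand-in for a site-specific
# template library). Each template names the target concepts that trigger
# it, its building-block slots with the unit each slot is standardized to,
# and a script body in which $('<slot>') placeholders are replaced by the
# matched (and unit-converted) source attributes.
templates:
  - name: bmi
    description: body-mass index from weight and height (kg/m^2)
    triggers: ["body mass index", "bmi"]
    conditional: false
    slots:
      weight:
        unit: kg
        synonyms: ["weight", "body weight"]
      height:
        unit: m
        synonyms: ["height", "length", "body length", "standing height", "stature"]
    body: "$('weight').div($('height').pow(2)).value()"
  - name: hypertension
    description: hypertension flag from blood-pressure cutoffs (SBP>=140 or DBP>=90)
    triggers: ["hypertension"]
    conditional: true
    slots:
      sbp:
        unit: mmHg
        synonyms: ["systolic blood pressure", "systolic"]
      dbp:
        unit: mmHg
        synonyms: ["diastolic blood pressure", "diastolic"]
    body: "$('sbp') >= 140 || $('dbp') >= 90 ? '1' : '0'"
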