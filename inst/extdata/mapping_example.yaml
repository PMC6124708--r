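# Column mapping example: canonical field -> column name in the source file.
# Use with read_cohort(path, mapping = "mapping_example.yaml") or the CLI
# `mapping:` config key when a cohort file does not use canonical headers.
id: patient_code
sex: gender
age: age_years
bmi: body_mass_index
neck_cm: neck_circumference
sys_bp: systolic_bp
dia_bp: diastolic_bp
ess: epworth_score
hypertension: htn
snoring: snores
tiredness: daytime_tiredness
observed_apnea: witnessed_apnea
ahi: ahi_events_per_hour
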