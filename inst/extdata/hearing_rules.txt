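# Default hearing-loss rule base: 18 declarative rules executed by forward
# chaining. Conditions are vectorized logical expressions over per-patient
# features (left_pta, right_pta, worse_pta, *_has_loss, *_evidence,
# conductive_any, sensorineural_any, has_loss_any) and over labels already
# inferred (hl_type, severity, laterality, treatment). Within a dimension,
# the lowest priority whose condition holds assigns the label.
version: 1

id: type_mixed
dimension: type
priority: 1
condition: conductive_any & sensorineural_any
assign: mixed
description: Both conductive and sensorineural characteristics detected in the same patient

id: type_conductive
dimension: type
priority: 2
condition: conductive_any & !sensorineural_any
assign: conductive
description: Conductive evidence (air-bone gap or abnormal tympanogram) without a sensorineural component

id: type_sensorineural
dimension: type
priority: 3
condition: !conductive_any & (sensorineural_any | has_loss_any)
assign: sensorineural
description: Sensorineural evidence, or hearing loss without conductive evidence (default adult etiology)

id: type_normal
dimension: type
priority: 4
condition: !conductive_any & !sensorineural_any & !has_loss_any
assign: normal
description: No hearing loss and no evidence in either ear

id: sev_normal
dimension: severity
priority: 1
condition: hl_type == "normal"
assign: normal
description: Normal hearing grades as normal severity

id: sev_profound
dimension: severity
priority: 2
condition: hl_type != "normal" & worse_pta > 90
assign: profound
description: Profound when the worse-ear pure-tone average exceeds 90 dB HL

id: sev_severe
dimension: severity
priority: 3
condition: hl_type != "normal" & worse_pta > 70
assign: severe
description: Severe for worse-ear PTA above 70 up to 90 dB HL

id: sev_moderate
dimension: severity
priority: 4
condition: hl_type != "normal" & worse_pta > 40
assign: moderate
description: Moderate for worse-ear PTA above 40 up to 70 dB HL

id: sev_mild
dimension: severity
priority: 5
condition: hl_type != "normal" & worse_pta <= 40
assign: mild
description: Mild for any remaining hearing loss (worse-ear PTA at most 40 dB HL)

id: lat_bilateral
dimension: laterality
priority: 1
condition: left_has_loss & right_has_loss
assign: bilateral
description: Bilateral when both ears demonstrate hearing loss

id: lat_left
dimension: laterality
priority: 2
condition: left_has_loss & !right_has_loss
assign: unilateral_left
description: Loss confined to the left ear

id: lat_right
dimension: laterality
priority: 3
condition: !left_has_loss & right_has_loss
assign: unilateral_right
description: Loss confined to the right ear

id: lat_normal
dimension: laterality
priority: 4
condition: !left_has_loss & !right_has_loss
assign: normal
description: Neither ear demonstrates hearing loss

id: tx_monitoring
dimension: treatment
priority: 1
condition: hl_type == "normal"
assign: monitoring
description: Normal hearing needs periodic monitoring only

id: tx_surgical
dimension: treatment
priority: 2
condition: hl_type == "conductive" | hl_type == "mixed"
assign: surgical_evaluation
description: Any conductive component warrants surgical evaluation

id: tx_cochlear
dimension: treatment
priority: 3
condition: hl_type == "sensorineural" & (severity == "severe" | severity == "profound") & laterality == "bilateral"
assign: cochlear_implant_evaluation
description: Cochlear-implant candidacy for bilateral severe-to-profound sensorineural loss (hearing-aid benefit not measurable in these data)

id: tx_hearing_aid
dimension: treatment
priority: 4
condition: hl_type == "sensorineural" & (severity == "mild" | severity == "moderate" | laterality != "bilateral")
assign: hearing_aid
description: Hearing aid for mild-to-moderate or unilateral sensorineural loss

id: tx_rehab_eligible
dimension: treatment
priority: 5
condition: treatment == "hearing_aid" | treatment == "cochlear_implant_evaluation"
assign: auditory_rehabilitation
kind: annotation
description: Aided patients are additionally eligible for auditory rehabilitation (trace flag, not a reassignment)
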