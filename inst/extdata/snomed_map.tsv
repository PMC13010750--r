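internal_label	concept_id	preferred_term	status
sensorineural	60700002	Sensorineural hearing loss	asserted
conductive	44057008	Conductive hearing loss	asserted
mixed	36885005	Mixed conductive AND sensorineural hearing loss	asserted
normal		Normal hearing	provisional
mild		Mild hearing loss	provisional
moderate		Moderate hearing loss	provisional
severe		Severe hearing loss	provisional
profound		Profound hearing loss	provisional
bilateral		Bilateral hearing loss	provisional
unilateral_left		Unilateral hearing loss, left	provisional
unilateral_right		Unilateral hearing loss, right	provisional
monitoring		Periodic monitoring	provisional
hearing_aid		Hearing aid provision	provisional
cochlear_implant_evaluation		Cochlear implant evaluation	provisional
surgical_evaluation		Surgical evaluation	provisional
auditory_rehabilitation		Auditory rehabilitation	provisional
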