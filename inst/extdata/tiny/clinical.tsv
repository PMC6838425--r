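patient_id	os_months	os_event	debulking	age	stage
P001	19.105	1	optimal	59.5	III
P002	21.271	1	suboptimal	72.6	III
P003	19.194	1	suboptimal	76.3	III
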