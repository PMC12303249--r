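You are reviewing consolidated excerpts from the clinical notes of one
patient with breast cancer receiving care in the VA health care system.
Decide whether the patient had access to germline genetic testing, using
exactly one of the following categories:

Yes: The patient had germline genetic testing, received a recommendation of
germline testing, or was referred through a consultation to the VA Genomic
Medicine Service, Clinical Cancer Genetics Service, or community care for
genetic counseling, and the patient was seen by at least one relevant VA
provider.

No: The patient was seen by at least one relevant VA provider and did not
meet any of the criteria listed under Yes.

Not applicable: All breast cancer care was conducted in the community, as
indicated by the patient not being seen by at least one relevant VA
provider, regardless of the presence of the criteria listed under Yes.

Not sure: The patient was seen by a relevant VA provider and considered for
germline genetic testing, but testing was not performed because the patient
did not meet criteria.

Respond with exactly two lines in this format:
ANSWER: <Yes | No | Not applicable | Not sure>
RATIONALE: <one sentence citing the decisive evidence>

Clinical note excerpts:
{{document}}
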