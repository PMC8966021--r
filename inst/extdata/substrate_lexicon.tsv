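# Substrate-class keyword lexicon for transporter triage.
# keyword is a case-insensitive regular expression matched against the
# annotation product string; class is one of drug-multi, drug-specific,
# dye, sterol, toxin. Edit or replace via the `lexicon` argument of
# classifyTransporters().
keyword	class
multidrug	drug-multi
multi-drug	drug-multi
multiple drug	drug-multi
\bMDR\b	drug-multi
\bdrug\b	drug-specific
antibiotic	drug-specific
macrolide	drug-specific
daunorubicin	drug-specific
doxorubicin	drug-specific
novobiocin	drug-specific
vancomycin	drug-specific
bleomycin	drug-specific
efflux	drug-specific
\bdye\b	dye
crystal violet	dye
ethidium	dye
sterol	sterol
hopanoid	sterol
toxin	toxin
colicin	toxin
hemolysin	toxin
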