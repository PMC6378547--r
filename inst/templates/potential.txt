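Thank you for completing {study_name} online survey. We have been experiencing fraud in the study and your survey entry has been flagged as suspicious. We sincerely apologize for the inconvenience if this was an error. Please contact us by calling {callback_number} to confirm that you did indeed complete a survey and we will send your incentive.
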