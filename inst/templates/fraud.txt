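You recently completed a survey for {study_name} online. However, we detected that your survey entry was fraudulent. If you think this is a mistake, please contact us by calling {callback_number}.
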