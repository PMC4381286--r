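pzbd_deleted	has_glnrs	has_glurs2	has_gatcab	consistent
FALSE	FALSE	FALSE	FALSE	TRUE
FALSE	FALSE	FALSE	TRUE	TRUE
FALSE	FALSE	TRUE	FALSE	TRUE
FALSE	FALSE	TRUE	TRUE	TRUE
FALSE	TRUE	FALSE	FALSE	TRUE
FALSE	TRUE	FALSE	TRUE	TRUE
FALSE	TRUE	TRUE	FALSE	TRUE
FALSE	TRUE	TRUE	TRUE	TRUE
TRUE	FALSE	FALSE	FALSE	TRUE
TRUE	FALSE	FALSE	TRUE	FALSE
TRUE	FALSE	TRUE	FALSE	TRUE
TRUE	FALSE	TRUE	TRUE	TRUE
TRUE	TRUE	FALSE	FALSE	TRUE
TRUE	TRUE	FALSE	TRUE	TRUE
TRUE	TRUE	TRUE	FALSE	TRUE
TRUE	TRUE	TRUE	TRUE	TRUE
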