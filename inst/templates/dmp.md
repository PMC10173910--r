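# Plano de Gestão de Dados

## Identificação do projeto

- **Nome do projeto:** {{{project_name}}}
- **Número do projeto:** {{{project_number}}}
- **Investigador(a) principal:** {{{principal_investigator}}}
- **Financiamento:** {{{funding}}}
- **Instituição coordenadora:** {{{institution}}}
- **Data de elaboração:** {{{plan_date}}}

## Dados e recursos do estudo

Descrição dos dados coletados, instrumentos de coleta, formatos e volumes
esperados, e recursos computacionais empregados.

{{{data_description}}}

## Segurança e privacidade

Medidas de proteção dos dados pessoais e sensíveis: controle de acesso,
criptografia, anonimização e identificação de campos com identificadores
pessoais nos metadados dos instrumentos.

{{{security_measures}}}

## Acesso, compartilhamento e arquivamento

Formas de acesso aos dados durante e após o estudo, política de
compartilhamento entre centros, repositórios de arquivamento e prazos de
retenção.

{{{access_and_archiving}}}

## Aspectos éticos e regulatórios

Aprovação por comitê de ética, consentimento dos participantes e conformidade
com a legislação de proteção de dados aplicável.

{{{ethics_and_regulatory}}}
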