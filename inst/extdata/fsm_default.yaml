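# Default controller table. Rows marked [documented] are the transitions the
# framework fixes; all other rows complete the table (REST backs out toward
# MAIN, RIGHT_HAND advances a cyclic highlight, BOTH_HANDS selects) and may
# be overridden by a user-supplied file.
initial: MAIN
text_entry:
  - EMAIL_COMPOSE
  - BROWSER_ADDRESS
transitions:
  MAIN:
    RIGHT_HAND: {to: BROWSER, action: launch_browser}        # [documented]
    LEFT_HAND: {to: OS_EXPLORER, action: launch_os_explorer} # [documented]
    BOTH_HANDS: {to: EMAIL, action: launch_email}            # [documented]
    REST: {to: MAIN, action: noop}
  BROWSER:
    RIGHT_HAND: {to: BROWSER, action: next_link}
    LEFT_HAND: {to: BROWSER, action: prev_link}
    BOTH_HANDS: {to: BROWSER_ADDRESS, action: enter_address}
    REST: {to: MAIN, action: close_browser}
  BROWSER_ADDRESS:
    RIGHT_HAND: {to: BROWSER_ADDRESS, action: noop}
    LEFT_HAND: {to: BROWSER_ADDRESS, action: noop}
    BOTH_HANDS: {to: BROWSER, action: confirm_address}
    REST: {to: BROWSER, action: cancel_entry}
  OS_EXPLORER:
    RIGHT_HAND: {to: OS_EXPLORER, action: next_item}
    LEFT_HAND: {to: OS_EXPLORER, action: prev_item}
    BOTH_HANDS: {to: OS_EXPLORER, action: open_item}
    REST: {to: MAIN, action: close_explorer}
  EMAIL:
    BOTH_HANDS: {to: EMAIL_INBOX, action: open_inbox}        # [documented]
    RIGHT_HAND: {to: EMAIL, action: next_folder}
    LEFT_HAND: {to: EMAIL_COMPOSE, action: compose_message}
    REST: {to: MAIN, action: close_email}
  EMAIL_INBOX:
    RIGHT_HAND: {to: EMAIL_INBOX, action: highlight_next}    # cycles open/reply/forward/delete/folders
    BOTH_HANDS: {to: EMAIL_INBOX, action: select_highlighted}
    LEFT_HAND: {to: EMAIL_COMPOSE, action: reply_message}
    REST: {to: EMAIL, action: back_to_folders}
  EMAIL_COMPOSE:
    RIGHT_HAND: {to: EMAIL_COMPOSE, action: noop}
    LEFT_HAND: {to: EMAIL_COMPOSE, action: noop}
    BOTH_HANDS: {to: EMAIL_INBOX, action: send_message}
    REST: {to: EMAIL, action: discard_message}
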